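# Shared fixtures and independent oracles for the test suite.

# The deterministic miniature cohort is expensive enough to build once.
.fixture_env <- new.env(parent = emptyenv())
get_fixture <- function() {
  if (is.null(.fixture_env$fx)) .fixture_env$fx <- fixture_small()
  .fixture_env$fx
}
get_fixture_filtered <- function() {
  if (is.null(.fixture_env$filt)) {
    fx <- get_fixture()
    .fixture_env$filt <- presence_filter(median_normalize(fx$matrix))$matrix
  }
  .fixture_env$filt
}

# A tiny fully-observed matrix with known values.
toy_matrix <- function(values, metabolites = NULL, samples = NULL,
                       layer = "raw", batch = NULL) {
  m <- matrix(values, nrow = if (is.null(metabolites)) 3 else length(metabolites))
  rownames(m) <- metabolites %||% paste0("met", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  peak_matrix(m, layer = layer, batch = batch)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_annotation <- function(sample_id, case_id, location, ...) {
  as_sample_annotation(data.frame(sample_id = sample_id, case_id = case_id,
                                  location = location, ...,
                                  stringsAsFactors = FALSE))
}

# Independent O(N) running-sum oracle for the enrichment score: builds the
# full profile position by position and takes the extreme deviation.
oracle_enrichment_score <- function(scores, hit_positions, p) {
  n <- length(scores)
  hit <- seq_len(n) %in% hit_positions
  w <- abs(scores)^p
  nr <- sum(w[hit])
  step <- numeric(n)
  step[hit] <- if (nr == 0) 1 / sum(hit) else w[hit] / nr
  if (any(!hit)) step[!hit] <- -1 / sum(!hit)
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

# Independent exact signed-rank p by explicit enumeration of all 2^n sign
# assignments (feasible for n <= 14).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  upper <- mean(w_all >= w_obs - 1e-9)
  lower <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(upper, lower))
}
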