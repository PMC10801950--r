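# internal helpers shared across modules

stop_koaev <- function(msg, class = "koaev_error") {
  cond <- structure(
    class = c(class, "koaev_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL runs on the current stream (non-reproducible by choice).
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Per-stage / per-repeat seed derivation: offset from a master seed, kept
# inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) + as.numeric(index)) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (1 = identical partitions, ~0 = random agreement).
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop_koaev("partitions must label the same items", "koaev_length_mismatch")
  }
  mclust::adjustedRandIndex(a, b)
}

#' Cluster purity against reference labels
#'
#' Fraction of items whose cluster's majority reference label matches their
#' own; in \[0, 1\], 1 meaning every cluster is label-pure.
#'
#' @param labels cluster labels.
#' @param truth reference labels (e.g. diagnosis).
#' @return A single number in \[0, 1\].
#' @export
cluster_purity <- function(labels, truth) {
  if (length(labels) != length(truth)) {
    stop_koaev("partitions must label the same items", "koaev_length_mismatch")
  }
  tab <- table(labels, truth)
  sum(apply(tab, 1, max)) / length(labels)
}
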