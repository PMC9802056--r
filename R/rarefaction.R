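#' Rarefaction configuration
#'
#' @param depth Target reads per sample. The study design this package
#'   follows rarefies at 10,114 reads; `NULL` (default) uses the minimum
#'   column sum of the table being rarefied.
#' @param repetitions Number of independent subsamples averaged into the
#'   mean table (default 100).
#' @param seed Integer seed making the whole mean table reproducible.
#' @return A list of class `rarefaction_config`.
#' @export
rarefaction_config <- function(depth = NULL, repetitions = 100L, seed = 1L) {
  if (!is.null(depth)) {
    depth <- as.integer(depth)
    if (is.na(depth) || depth < 1) stop("depth must be a positive integer")
  }
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1)
    stop("repetitions must be a positive integer")
  structure(list(depth = depth, repetitions = repetitions,
                 seed = as.integer(seed)),
            class = "rarefaction_config")
}

# Deterministic per-sample sub-seed so that dropping one sample never
# perturbs another sample's draws. Simple polynomial string hash mod 2^31-1.
sample_seed <- function(seed, sample_id, rep = 0L) {
  h <- 0
  for (ch in utf8ToInt(sample_id)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + seed * 7919 + rep * 104729) %% 2147483647)
}

# One multivariate-hypergeometric draw: subsample `depth` reads without
# replacement from integer count vector `x`. Index-based, O(total reads)
# in C via sample.int + findInterval.
subsample_column <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(x)
  cum <- cumsum(x)
  idx <- sample.int(total, depth)
  tabulate(findInterval(idx - 0.5, c(0, cum)), nbins = length(x))
}

#' Rarefy each sample once to a common depth
#'
#' Uniform random subsampling without replacement (multivariate
#' hypergeometric), the classical behaviour of QIIME's repeated even-depth
#' rarefaction. Each sample draws from its own random stream derived from
#' `(seed, sample id)`, so removing a sample leaves the others' draws
#' untouched.
#'
#' @param table A raw integer [count_table()].
#' @param depth Target reads per sample; every column sum must be >= depth.
#' @param seed Integer seed.
#' @return A [count_table()] with every column summing exactly to `depth`.
#' @examples
#' m <- matrix(c(8L, 2L), ncol = 1, dimnames = list(c("a", "b"), "s1"))
#' rarefy_once(count_table(m, "DNA"), depth = 5, seed = 1)
#' @export
rarefy_once <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (!isTRUE(attr(table, "raw")))
    stop("rarefaction operates on raw integer tables")
  depth <- as.integer(depth)
  cs <- colSums(table)
  short <- cs < depth
  if (any(short))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(colnames(table)[short], collapse = ", "))
  out <- unclass(table)
  for (j in seq_len(ncol(out))) {
    set.seed(sample_seed(seed, colnames(out)[j]))
    out[, j] <- subsample_column(out[, j], depth)
  }
  count_table(out, attr(table, "molecule"), raw = TRUE)
}

#' Mean of repeated rarefactions
#'
#' Draws `repetitions` independent rarefactions of each sample and returns
#' the entrywise mean. Integer totals are accumulated and divided once, so
#' every column of the mean table sums to `depth` exactly. Entries may be
#' fractional; an OTU observed in any repetition keeps a positive mean count
#' ("detected" downstream means mean count > 0).
#'
#' @param table A raw integer [count_table()].
#' @param cfg A [rarefaction_config()]; a `NULL` depth defaults to the
#'   minimum column sum.
#' @return A non-raw [count_table()] of mean counts.
#' @export
rarefy_mean <- function(table, cfg = rarefaction_config()) {
  stopifnot(inherits(table, "count_table"), inherits(cfg, "rarefaction_config"))
  if (!isTRUE(attr(table, "raw")))
    stop("rarefaction operates on raw integer tables")
  depth <- if (is.null(cfg$depth)) as.integer(min(colSums(table))) else cfg$depth
  cs <- colSums(table)
  short <- cs < depth
  if (any(short))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(colnames(table)[short], collapse = ", "))
  x <- unclass(table)
  acc <- matrix(0, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    for (r in seq_len(cfg$repetitions)) {
      set.seed(sample_seed(cfg$seed, colnames(x)[j], r - 1L))
      acc[, j] <- acc[, j] + subsample_column(col, depth)
    }
  }
  count_table(acc / cfg$repetitions, attr(table, "molecule"), raw = FALSE)
}
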