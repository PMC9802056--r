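#' @keywords internal
"_PACKAGE"

#' Ordered habitat continuum
#'
#' The default habitat chain, ordered along the flow path. Upstream habitats
#' come first; source attribution scans this vector left to right. Longer
#' chains are accepted everywhere a `habitats` argument is exposed.
#'
#' @return Character vector of habitat labels, most upstream first.
#' @export
habitat_levels <- function() c("river", "vegetated", "lake")

#' Construct a validated OTU count table
#'
#' A count table is an OTU x sample numeric matrix carrying a `molecule` tag
#' (`"DNA"` for the 16S rRNA gene, `"RNA"` for the transcript sequenced as
#' cDNA). Raw tables must be integer-valued with every sample column sum
#' positive; mean-rarefied tables may hold fractional counts.
#'
#' @param counts Numeric matrix, one row per OTU, one column per sample.
#'   Row and column names are required and must be unique.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param raw Logical; if `TRUE` (default) enforce integer entries and
#'   positive column sums.
#' @return A `count_table`: the matrix with attributes `molecule` and `raw`.
#' @examples
#' m <- matrix(c(5, 1, 0, 0, 2, 0), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' ct <- count_table(m, "DNA")
#' colSums(ct)
#' @export
count_table <- function(counts, molecule = c("DNA", "RNA"), raw = TRUE) {
  molecule <- match.arg(molecule)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs OTU row names and sample column names")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(counts))
    stop("count table contains missing values")
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]))
  }
  if (raw) {
    if (any(counts != trunc(counts)))
      stop("raw count table must be integer-valued")
    if (ncol(counts) > 0 && any(colSums(counts) <= 0))
      stop("raw table has empty sample column(s): ",
           paste(colnames(counts)[colSums(counts) <= 0], collapse = ", "))
  }
  structure(counts, molecule = molecule, raw = raw, class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s, %d OTUs x %d samples (%s)\n",
              attr(x, "molecule"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "raw"))) "raw integer counts" else "mean-rarefied"))
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-delimited file with OTU identifiers in the first column and
#' sample identifiers in the header row; preserves file order.
#'
#' @param path Path to a TSV file.
#' @inheritParams count_table
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, molecule = c("DNA", "RNA"), raw = TRUE) {
  molecule <- match.arg(molecule)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs at least one sample column: ", path)
  otus <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(otus, colnames(df)[-1]))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d (OTU '%s'), column '%s' in %s",
                 idx[1], otus[idx[1]], colnames(num)[idx[2]], path))
  }
  if (raw && all(num == trunc(num)) && max(num) <= .Machine$integer.max)
    storage.mode(num) <- "integer"
  count_table(num, molecule, raw = raw)
}

#' Write an OTU count table to TSV
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(otu_id = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `habitat`, `campaign`,
#' `site_index`, `pair_id` and optionally `molecule`. Habitat labels are
#' matched case-insensitively onto the habitat chain. A `pair_id` joins one
#' DNA sample to its matching RNA sample.
#'
#' @param path Path to a TSV file.
#' @param habitats Ordered habitat chain (default [habitat_levels()]).
#' @return A `data.frame` with one row per sample; `habitat` is an ordered
#'   factor along the continuum.
#' @export
read_sample_info <- function(path, habitats = habitat_levels()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  validate_sample_info(df, habitats)
}

#' Validate a sample metadata data.frame
#'
#' @param df Data frame with the columns described in [read_sample_info()].
#' @inheritParams read_sample_info
#' @return The validated data frame, habitat coerced to an ordered factor.
#' @export
validate_sample_info <- function(df, habitats = habitat_levels()) {
  need <- c("sample_id", "habitat", "campaign", "site_index", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample info is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    df$habitat <- factor(character(), levels = habitats, ordered = TRUE)
    return(df)
  }
  hab <- tolower(trimws(df$habitat))
  bad <- unique(df$habitat[!hab %in% habitats])
  if (length(bad))
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(habitats, collapse = " < "), ")")
  df$habitat <- factor(hab, levels = habitats, ordered = TRUE)
  df$site_index <- as.integer(df$site_index)
  if (anyNA(df$site_index) || any(df$site_index < 1))
    stop("site_index must be an integer >= 1")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("molecule" %in% names(df)) {
    df$molecule <- toupper(df$molecule)
    if (!all(df$molecule %in% c("DNA", "RNA")))
      stop("molecule column must be DNA or RNA")
    two <- tapply(df$molecule, df$pair_id, function(m) any(duplicated(m)))
    if (any(two))
      stop("pair_id bound to two samples of the same molecule: ",
           paste(names(two)[two], collapse = ", "))
  }
  # within (campaign, habitat, molecule) site indices must be unique
  key <- paste(df$campaign, df$habitat,
               if ("molecule" %in% names(df)) df$molecule else "", sep = "\r")
  dup <- tapply(df$site_index, key, anyDuplicated)
  if (any(dup > 0))
    stop("duplicate site_index within (campaign, habitat)")
  df
}

#' Write sample metadata to TSV
#' @param info Sample info data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(info, path) {
  out <- info
  out$habitat <- as.character(out$habitat)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-OTU 16S rRNA gene copy-number table
#'
#' Tab-delimited, columns `otu_id` and `copies` (rrnDB-style estimates of
#' 16S gene copies per genome). Missing OTUs are simply absent from the
#' table, never recorded as zero.
#'
#' @param path Path to a TSV file.
#' @return Named numeric vector of copy numbers keyed by OTU id.
#' @export
read_copy_numbers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("otu_id", "copies") %in% names(df)))
    stop("copy-number table needs columns otu_id, copies")
  copies <- as.numeric(df$copies)
  if (anyNA(copies) || any(copies <= 0))
    stop("copy numbers must be positive reals")
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in copy-number table")
  stats::setNames(copies, df$otu_id)
}

#' Read per-sample flow-cytometry total cell counts
#'
#' Tab-delimited, columns `sample_id` and `cells_per_ml`.
#'
#' @param path Path to a TSV file.
#' @return Named numeric vector of cell densities keyed by sample id.
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("sample_id", "cells_per_ml") %in% names(df)))
    stop("cell-count table needs columns sample_id, cells_per_ml")
  cells <- as.numeric(df$cells_per_ml)
  if (anyNA(cells) || any(cells <= 0))
    stop("cell counts must be strictly positive")
  stats::setNames(cells, df$sample_id)
}

#' Align DNA and RNA tables into a paired view
#'
#' Matches DNA and RNA sample columns through the `pair_id` column of the
#' metadata, unions the OTU sets of both tables (filling absent rows with
#' exact zero), and drops pairs missing either member with a warning - a
#' half-pair is unusable for ratio work but should not sink the run.
#'
#' @param dna,rna [count_table()] objects tagged DNA and RNA.
#' @param info Sample metadata (see [read_sample_info()]); must contain a
#'   `molecule` column, or sample ids must match columns of exactly one
#'   table each.
#' @param habitats Ordered habitat chain.
#' @return A `paired_tables` object: list with elements `dna` and `rna`
#'   (matrices with identical row and column order, columns named by
#'   `pair_id`), and `pairs` (per-pair metadata: pair_id, campaign, habitat,
#'   site_index, dna_sample, rna_sample).
#' @export
align_pairs <- function(dna, rna, info, habitats = habitat_levels()) {
  if (!identical(attr(dna, "molecule"), "DNA") ||
      !identical(attr(rna, "molecule"), "RNA"))
    stop("`dna` and `rna` must be count tables tagged DNA and RNA")
  info <- validate_sample_info(as.data.frame(info), habitats)
  if (nrow(info) == 0) stop("empty sample info: nothing to pair")

  if (!"molecule" %in% names(info)) {
    info$molecule <- ifelse(info$sample_id %in% colnames(dna), "DNA",
                     ifelse(info$sample_id %in% colnames(rna), "RNA", NA))
    if (anyNA(info$molecule))
      stop("sample(s) in metadata not found in either table: ",
           paste(info$sample_id[is.na(info$molecule)], collapse = ", "))
  }
  d_info <- info[info$molecule == "DNA", , drop = FALSE]
  r_info <- info[info$molecule == "RNA", , drop = FALSE]
  d_info <- d_info[d_info$sample_id %in% colnames(dna), , drop = FALSE]
  r_info <- r_info[r_info$sample_id %in% colnames(rna), , drop = FALSE]

  common <- intersect(d_info$pair_id, r_info$pair_id)
  orphan <- setdiff(union(d_info$pair_id, r_info$pair_id), common)
  if (length(orphan))
    warning("excluding unmatched pair_id(s) lacking a DNA or RNA partner: ",
            paste(sort(orphan), collapse = ", "))
  if (!length(common)) stop("no complete DNA/RNA pairs to align")

  d_info <- d_info[match(common, d_info$pair_id), , drop = FALSE]
  r_info <- r_info[match(common, r_info$pair_id), , drop = FALSE]
  if (!identical(as.character(d_info$habitat), as.character(r_info$habitat)) ||
      !identical(d_info$campaign, r_info$campaign))
    stop("paired DNA and RNA samples disagree on habitat or campaign")

  otus <- union(rownames(dna), rownames(rna))
  expand <- function(tab, ids) {
    m <- matrix(0, nrow = length(otus), ncol = length(ids),
                dimnames = list(otus, ids))
    m[rownames(tab), ] <- unclass(tab)[, ids, drop = FALSE]
    m
  }
  pairs <- data.frame(pair_id = common,
                      campaign = d_info$campaign,
                      habitat = factor(as.character(d_info$habitat),
                                       levels = habitats, ordered = TRUE),
                      site_index = d_info$site_index,
                      dna_sample = d_info$sample_id,
                      rna_sample = r_info$sample_id,
                      stringsAsFactors = FALSE)
  ord <- order(pairs$campaign, pairs$habitat, pairs$site_index)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  d <- expand(dna, pairs$dna_sample); colnames(d) <- pairs$pair_id
  r <- expand(rna, pairs$rna_sample); colnames(r) <- pairs$pair_id
  structure(list(dna = d, rna = r, pairs = pairs, habitats = habitats),
            class = "paired_tables")
}

#' @export
print.paired_tables <- function(x, ...) {
  cat(sprintf("<paired_tables> %d OTUs x %d DNA/RNA pairs; campaigns: %s\n",
              nrow(x$dna), nrow(x$pairs),
              paste(unique(x$pairs$campaign), collapse = ", ")))
  invisible(x)
}

#' Restrict a paired view to one campaign
#'
#' @param paired A `paired_tables` object.
#' @param campaign Campaign label.
#' @return A `paired_tables` restricted to that campaign's pairs.
#' @export
subset_campaign <- function(paired, campaign) {
  stopifnot(inherits(paired, "paired_tables"))
  keep <- paired$pairs$campaign == campaign
  if (!any(keep)) stop("no pairs for campaign '", campaign, "'")
  structure(list(dna = paired$dna[, keep, drop = FALSE],
                 rna = paired$rna[, keep, drop = FALSE],
                 pairs = paired$pairs[keep, , drop = FALSE],
                 habitats = paired$habitats),
            class = "paired_tables")
}
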