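#' Construct a metabolite concentration matrix
#'
#' Lightweight container for a samples x metabolites concentration table.
#' Rows are samples, columns are metabolite measures identified by their
#' conventional abbreviations (e.g. \code{"XXL-VLDL-L"}, \code{"Ile"}).
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#' @param sample_ids character vector of sample identifiers (defaults to
#'   rownames of \code{values}).
#' @param metabolite_ids character vector of metabolite abbreviations
#'   (defaults to colnames of \code{values}); must be unique.
#' @param residualized logical; \code{TRUE} once covariate residualization
#'   has been applied (see [residualize_on_covariates()]).
#' @return An object of class \code{metab_matrix}: a list with elements
#'   \code{values}, \code{sample_ids}, \code{metabolite_ids},
#'   \code{residualized}.
#' @examples
#' m <- metab_matrix(matrix(rnorm(20), 10, 2,
#'                   dimnames = list(NULL, c("Ile", "Leu"))))
#' dim(m$values)
#' @export
metab_matrix <- function(values, sample_ids = rownames(values),
                         metabolite_ids = colnames(values),
                         residualized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  if (is.null(metabolite_ids)) {
    stop("metabolite ids are required (column names or `metabolite_ids`)")
  }
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (ncol(values) < 2L) stop("at least two metabolites are required")
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(metabolite_ids) != ncol(values)) {
    stop("length(metabolite_ids) must equal ncol(values)")
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "))
  }
  if (any(is.infinite(values))) stop("non-finite metabolite values")
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 metabolite_ids = metabolite_ids,
                 residualized = isTRUE(residualized)),
            class = "metab_matrix")
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf("metab_matrix: %d samples x %d metabolites (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$residualized) "residualized" else "raw"))
  cat("metabolites:",
      paste(utils::head(x$metabolite_ids, 8), collapse = ", "),
      if (length(x$metabolite_ids) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

#' Construct a genotype dosage matrix
#'
#' Samples x SNPs matrix of minor-allele dosages in \{0, 1, 2, NA\} together
#' with per-marker metadata. Dosages count copies of the \emph{minor} allele
#' (see [recode_minor_allele()]).
#'
#' @param dosages numeric matrix of 0/1/2/NA values, samples in rows.
#' @param markers data.frame with one row per SNP and columns \code{id},
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt},
#'   \code{minor}.
#' @param sample_ids character vector of sample identifiers.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, markers, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) == 0L) stop("empty marker set")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(dosages)))
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(markers))) {
    stop("markers must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(markers) != ncol(dosages)) {
    stop("nrow(markers) must equal ncol(dosages)")
  }
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (any(markers$pos <= 0 | markers$pos != round(markers$pos))) {
    stop("marker positions must be positive integers (1-based)")
  }
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop("dosages must lie in {0, 1, 2, NA}; offending values: ",
         paste(utils::head(unique(dosages[bad]), 5), collapse = ", "))
  }
  dimnames(dosages) <- list(as.character(sample_ids), markers$id)
  structure(list(dosages = dosages, markers = markers,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Enumerate the canonical unordered metabolite pairs
#'
#' All M(M-1)/2 unordered pairs in canonical order: within each pair the two
#' ids are sorted lexicographically (\code{metabolite_1 < metabolite_2}), and
#' the pairs themselves are returned sorted. 38 metabolites give 703 pairs.
#'
#' @param ids character vector of (unique) node identifiers.
#' @return data.frame with columns \code{metabolite_1}, \code{metabolite_2}.
#' @examples
#' nrow(canonical_pairs(paste0("m", 1:38)))  # 703
#' @export
canonical_pairs <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(ids) < 2L) {
    return(data.frame(metabolite_1 = character(), metabolite_2 = character(),
                      stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(sort(ids), 2L)
  data.frame(metabolite_1 = cmb[1L, ], metabolite_2 = cmb[2L, ],
             stringsAsFactors = FALSE)
}

# canonical "a||b" key for an unordered pair (internal)
pair_key <- function(m1, m2) {
  paste(pmin(m1, m2), pmax(m1, m2), sep = "||")
}
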