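# I/O for every external representation the pipeline touches:
# delimited metabolite/covariate tables, VCF or additive-coded genotypes,
# gene annotation, edge lists, association tables, GraphML.

#' Read a samples x metabolites concentration table
#'
#' The first row is a header of metabolite abbreviations, the first column
#' holds sample identifiers. Cells equal to \code{missing_token} (or empty)
#' are parsed as missing.
#'
#' @param path file path.
#' @param delimiter field delimiter; tab by default, use \code{","} for CSV.
#' @param missing_token string treated as missing (in addition to empty
#'   cells); default \code{"NA"}.
#' @return A [metab_matrix()] with \code{residualized = FALSE}.
#' @export
read_metabolite_table <- function(path, delimiter = "\t",
                                  missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 3L) stop("expected a sample-id column plus >= 2 metabolites")
  ids <- names(raw)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate metabolite id in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sample_ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals == missing_token | vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at sample '%s', metabolite '%s'",
                 vals[bad][1L], sample_ids[w[1L]], ids[w[2L]]))
  }
  metab_matrix(num, sample_ids = sample_ids, metabolite_ids = ids,
               residualized = FALSE)
}

#' Read a sample covariate table
#'
#' Expects a header with at least \code{sample_id}; conventional covariates
#' are \code{sex} (binary 0/1 code) and \code{bmi} (kg/m^2, positive).
#'
#' @param path file path.
#' @param delimiter field delimiter.
#' @return data.frame with unique \code{sample_id}.
#' @export
read_covariate_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  cov <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(cov)) {
    names(cov)[1L] <- "sample_id"
  }
  cov$sample_id <- as.character(cov$sample_id)
  if (anyDuplicated(cov$sample_id)) stop("duplicate sample ids in covariates")
  if ("bmi" %in% names(cov) && any(!is.na(cov$bmi) & cov$bmi <= 0)) {
    stop("bmi must be positive where present")
  }
  cov
}

#' Recode a dosage matrix to count the minor allele
#'
#' Allele frequency is recomputed from the data per marker; if the coded
#' allele's frequency exceeds 0.5 the marker is flipped (0 <-> 2). A tie at
#' exactly 0.5 keeps the coded (alternate) allele as "minor". The operation
#' is idempotent.
#'
#' @param genotypes a [genotype_matrix()].
#' @return The recoded [genotype_matrix()]; \code{markers$minor} records the
#'   minor allele where ref/alt labels are available.
#' @export
recode_minor_allele <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  freq <- colMeans(dos, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  mk <- genotypes$markers
  if (all(c("ref", "alt") %in% names(mk))) {
    mk$minor <- ifelse(flip, mk$ref, mk$alt)
  }
  genotype_matrix(dos, mk, genotypes$sample_ids)
}

#' Read genotypes from VCF or an additive-coded matrix
#'
#' For VCF, only the GT field is used; biallelic sites are retained and
#' multiallelic records skipped with a warning; \code{"./."} and \code{"."}
#' are missing. For \code{additive_matrix}, the file is a delimited table of
#' 0/1/2/NA values with a SNP header and sample-id first column, accompanied
#' by marker metadata columns or defaults. In both cases dosages are recoded
#' to count the minor allele (see [recode_minor_allele()]).
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"additive_matrix"}.
#' @param delimiter delimiter for \code{additive_matrix} input.
#' @return A [genotype_matrix()] with minor-allele dosages.
#' @export
read_genotypes <- function(path, format = c("vcf", "additive_matrix"),
                           delimiter = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gm <- switch(format,
               vcf = read_genotypes_vcf(path),
               additive_matrix = read_genotypes_additive(path, delimiter))
  recode_minor_allele(gm)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic VCF record(s) skipped")
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("empty marker set after filtering")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # alt-allele count from GT strings; phased or unphased
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- apply(gt_clean, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.")) return(NA_real_)
    al <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  })
  bad <- !is.na(dos) & !(dos %in% c(0, 1, 2))
  if (any(bad)) stop("genotype with more than 2 alternate alleles")
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], ":", fix[miss_id, "POS"])
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        minor = fix[, "ALT"], stringsAsFactors = FALSE)
  genotype_matrix(t(dos), markers, sample_ids = colnames(gt))
}

read_genotypes_additive <- function(path, delimiter) {
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = 1L)
  dos <- as.matrix(tab)
  if (ncol(dos) == 0L) stop("empty marker set")
  bad <- !(dos %in% c(0, 1, 2)) & !is.na(dos)
  if (any(bad)) {
    stop("additive matrix contains values outside {0, 1, 2, NA}")
  }
  markers <- data.frame(id = colnames(dos), chrom = NA_character_,
                        pos = seq_len(ncol(dos)),
                        ref = NA_character_, alt = NA_character_,
                        minor = NA_character_, stringsAsFactors = FALSE)
  genotype_matrix(dos, markers, sample_ids = rownames(dos))
}

#' Read a gene annotation table
#'
#' Delimited table with columns \code{gene}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive).
#'
#' @param path file path.
#' @param delimiter field delimiter.
#' @return data.frame of gene intervals.
#' @export
read_annotation_table <- function(path, delimiter = "\t") {
  ann <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(ann))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(ann$start > ann$end)) stop("annotation interval with start > end")
  ann
}

# numeric formatting used by all writers: 6 significant digits for
# correlation-scale quantities, scientific notation for p-values
fmt_cor <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6,
                                                      format = "g"))
fmt_p <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6,
                                                    format = "e"))

#' Write a differential network as a tab-separated edge list
#'
#' Columns: \code{metabolite_1}, \code{metabolite_2}, \code{delta_pcorr},
#' \code{p_value}, \code{sign}. An empty network yields a header-only file.
#'
#' @param network a [differential_network()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "differential_network"))
  e <- network$edges
  out <- data.frame(metabolite_1 = e$metabolite_1,
                    metabolite_2 = e$metabolite_2,
                    delta_pcorr = fmt_cor(e$delta),
                    p_value = fmt_p(e$p_perm),
                    sign = e$sign, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path file path.
#' @param nodes optional node set; defaults to the union of edge endpoints.
#' @param threshold,B metadata to attach (not stored in the file).
#' @return A [differential_network()].
#' @export
read_edge_list <- function(path, nodes = NULL, threshold = NA_real_,
                           B = NA_integer_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(tab$metabolite_1, tab$metabolite_2)))
  }
  edges <- data.frame(metabolite_1 = as.character(tab$metabolite_1),
                      metabolite_2 = as.character(tab$metabolite_2),
                      delta = as.numeric(tab$delta_pcorr),
                      p_perm = as.numeric(tab$p_value),
                      sign = as.integer(tab$sign),
                      stringsAsFactors = FALSE)
  differential_network(nodes = nodes, edges = edges, threshold = threshold,
                       B = B)
}

#' Write a GWCA association table
#'
#' Tab-separated, mirroring the usual locus-table layout (snp, chromosome,
#' position, p_value, candidate_gene) plus the test internals r_A, r_B,
#' n_A, n_B, Z and the tested metabolite pair.
#'
#' @param records data.frame as returned by [run_gwca()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_association_table <- function(records, path) {
  cand <- if ("candidate_gene" %in% names(records)) {
    records$candidate_gene
  } else NA_character_
  out <- data.frame(snp = records$snp, chromosome = records$chrom,
                    position = records$pos,
                    metabolite_1 = records$metabolite_1,
                    metabolite_2 = records$metabolite_2,
                    n_A = records$n_A, n_B = records$n_B,
                    r_A = fmt_cor(records$r_A), r_B = fmt_cor(records$r_B),
                    Z = fmt_cor(records$Z), p_value = fmt_p(records$p),
                    significant = records$significant,
                    candidate_gene = cand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a differential network as GraphML
#'
#' @param network a [differential_network()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graphml_network <- function(network, path) {
  stopifnot(inherits(network, "differential_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("metabolite_1", "metabolite_2", "delta", "p_perm",
                      "sign")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
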