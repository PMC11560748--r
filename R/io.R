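#' Write / read a chemistry table as TSV
#'
#' Columns: sample_id, treatment, replicate, SOM, AN, AP, AK, pH, EC.
#' @param chem chemistry table.
#' @param path file path.
#' @return `read_chemistry`: the table; `write_chemistry`: `path`,
#'   invisibly.
#' @export
write_chemistry <- function(chem, path) {
  utils::write.table(chem, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_chemistry
#' @export
read_chemistry <- function(path) {
  chem <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "replicate")
  miss <- setdiff(need, names(chem))
  if (length(miss))
    stop("chemistry TSV missing column(s): ", paste(miss, collapse = ", "))
  chem
}

#' Write / read a community matrix as TSV
#'
#' Rows are OTUs, columns are samples, plus a trailing `taxonomy`
#' column with the semicolon-delimited lineage
#' `domain;phylum;genus`.
#'
#' @param cm a [community_matrix()].
#' @param path file path.
#' @param domain domain tag used when reading.
#' @return `read_community`: a [community_matrix()];
#'   `write_community`: `path`, invisibly.
#' @export
write_community <- function(cm, path) {
  tab <- as.data.frame(t(cm$counts))
  tab <- cbind(otu_id = colnames(cm$counts), tab,
               taxonomy = paste(cm$taxonomy$domain, cm$taxonomy$phylum,
                                cm$taxonomy$genus, sep = ";"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path, domain = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("otu_id", "taxonomy") %in% names(tab)))
    stop("community TSV needs otu_id and taxonomy columns")
  lineage <- strsplit(tab$taxonomy, ";", fixed = TRUE)
  ranks <- t(vapply(lineage, function(x) {
    length(x) <- 3L
    x
  }, character(3L)))
  counts <- t(as.matrix(tab[, setdiff(names(tab), c("otu_id", "taxonomy")),
                            drop = FALSE]))
  colnames(counts) <- tab$otu_id
  if (is.null(domain)) domain <- ranks[1L, 1L]
  taxonomy <- data.frame(otu_id = tab$otu_id, domain = ranks[, 1L],
                         phylum = ranks[, 2L], genus = ranks[, 3L])
  community_matrix(counts, taxonomy, domain)
}

#' Write a distance matrix as a square TSV
#' @param d a `dist` or matrix.
#' @param path file path.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate chemistry and community inputs
#'
#' Pure diagnostics (nothing is mutated): schema of the chemistry
#' table, per-domain sample alignment with the community matrices,
#' count positivity and integrality. Returns a character vector of
#' findings; empty when everything is well-formed.
#'
#' @param chem chemistry table.
#' @param communities named list of [community_matrix()]-like objects.
#' @return character vector of diagnostics.
#' @export
validate_inputs <- function(chem, communities = list()) {
  diags <- character()
  need <- c("sample_id", "treatment", "replicate", sq_indicators)
  miss <- setdiff(need, names(chem))
  if (length(miss))
    diags <- c(diags, paste0("chemistry: missing column(s) ",
                             paste(miss, collapse = ", ")))
  if (anyDuplicated(chem$sample_id))
    diags <- c(diags, "chemistry: duplicate sample_id values")
  for (ind in intersect(sq_indicators, names(chem))) {
    bad <- !is.finite(chem[[ind]])
    if (any(bad))
      diags <- c(diags, paste0("chemistry: non-finite ", ind, " for ",
                               paste(chem$sample_id[bad], collapse = ", ")))
  }
  for (dom in names(communities)) {
    cm <- communities[[dom]]
    counts <- cm$counts
    absent <- setdiff(chem$sample_id, rownames(counts))
    if (length(absent))
      diags <- c(diags, paste0(dom, ": community table missing sample(s) ",
                               paste(absent, collapse = ", ")))
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
    if (nrow(bad))
      diags <- c(diags, paste0(
        dom, ": non-integral or negative count at ",
        paste(apply(bad, 1L, function(rc)
          paste0(rownames(counts)[rc[1L]], "/", colnames(counts)[rc[2L]])),
          collapse = ", ")))
    zero <- rowSums(counts) == 0
    if (any(zero))
      diags <- c(diags, paste0(dom, ": all-zero sample(s) ",
                               paste(rownames(counts)[zero], collapse = ", ")))
  }
  diags
}
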