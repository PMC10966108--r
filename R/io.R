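#' Read and write pedigree tables
#'
#' Pedigrees are plain TSV with columns `id`, `father_id`, `mother_id`,
#' `sex` (1 = male, 2 = female) and `generation`. Missing parents are coded
#' `0`, the PLINK `.fam` convention for founders. Extra columns (breeding
#' values, phenotypes) are preserved on write and ignored by consumers that
#' do not need them.
#'
#' @param ped A pedigree data frame.
#' @param path File path.
#' @return `read_pedigree()` returns the pedigree data frame;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(all(c("id", "father_id", "mother_id", "sex", "generation")
                %in% names(ped)))
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "father_id", "mother_id", "sex", "generation")
                %in% names(ped)))
  ped
}

#' Restrict a pedigree to recent generations
#'
#' Keeps individuals at or after `min_generation` and recodes parents that
#' fall outside the window as founders (id 0), so the result is again a
#' valid self-contained pedigree. Useful for analyzing the near-equilibrium
#' tail of a long simulation.
#'
#' @param ped Pedigree data frame.
#' @param min_generation First generation to keep.
#' @return The truncated pedigree.
#' @export
truncate_pedigree <- function(ped, min_generation) {
  out <- ped[ped$generation >= min_generation, , drop = FALSE]
  keep <- out$id
  out$father_id[!(out$father_id %in% keep)] <- 0L
  out$mother_id[!(out$mother_id %in% keep)] <- 0L
  rownames(out) <- NULL
  out
}

#' Read a polygenic-index table
#'
#' Plain TSV with an `id` column, one or more PGI columns, and optional
#' covariate columns (`cov1`, `cov2`, ...). Missing PGI values (ungenotyped
#' individuals) are `NA`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_pgi_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot("id" %in% names(tab))
  tab
}
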