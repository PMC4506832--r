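#' Read and write cohort tables as TSV
#'
#' Cohort tables are exchanged as tab-separated text with a header row, one
#' row per (subject, electrode). `read_cohort()` restores the factor
#' codings used throughout the package (scala vestibuli, slim straight
#' array and progressive SNHL as reference levels) and checks the minimal
#' column roster.
#'
#' @param file Path to a TSV file.
#' @param table Cohort data frame.
#' @return `read_cohort()` returns the cohort data frame; `write_cohort()`
#'   returns `file` invisibly.
#' @export
read_cohort <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "electrode", "array_type")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("scalar" %in% names(tab)) {
    tab$scalar <- factor(tab$scalar, levels = c("SV", "ST"))
  }
  if ("array_type" %in% names(tab)) {
    lev <- c("SSA", "PMA", "SA")
    tab$array_type <- factor(tab$array_type,
                             levels = c(lev, setdiff(unique(tab$array_type),
                                                     lev)))
    tab$array_type <- droplevels(tab$array_type)
  }
  if ("etiology" %in% names(tab)) {
    lev <- c("ProgressiveSNHL", "Viral", "Genetic", "Autoimmune",
             "Ototoxic", "Otosclerosis")
    tab$etiology <- factor(tab$etiology,
                           levels = c(lev, setdiff(unique(tab$etiology),
                                                   lev)))
    tab$etiology <- droplevels(tab$etiology)
  }
  tab
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
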