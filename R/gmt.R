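#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, name, description, then
#' member genes.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene-sets to a GMT file
#'
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled; default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene-sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
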