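#' F2 genotype matrix container
#'
#' Holds raw genotype calls for an F2 mapping population plus the two parent
#' rows. SNP markers are codominant with calls `AA`/`AB`/`BB`/`NN`; PAV
#' (presence/absence variant) markers are dominant with calls `P`/`A`/`NN`
#' (`NN` = missing throughout).
#'
#' @param calls character matrix, individuals x markers, with row and column
#'   names.
#' @param individuals data frame with columns `id`, `role`
#'   (`"parent1"`, `"parent2"` or `"F2"`) and `batch` (sequencing pool label,
#'   may be `NA`).
#' @param markers data frame with columns `id` and `type`
#'   (`"SNP"` or `"PAV"`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals, markers) {
  stopifnot(is.matrix(calls), is.data.frame(individuals), is.data.frame(markers))
  if (nrow(calls) != nrow(individuals) || ncol(calls) != nrow(markers))
    stop_bad("calls dimensions (%d x %d) do not match metadata (%d x %d)",
             nrow(calls), ncol(calls), nrow(individuals), nrow(markers))
  if (sum(individuals$role == "parent1") != 1L ||
      sum(individuals$role == "parent2") != 1L)
    stop_bad("exactly one parent1 and one parent2 row required")
  if (!all(markers$type %in% c("SNP", "PAV")))
    stop_bad("marker types must be SNP or PAV")
  snp <- markers$type == "SNP"
  bad_snp <- !(calls[, snp, drop = FALSE] %in% c("AA", "AB", "BB", "NN"))
  bad_pav <- !(calls[, !snp, drop = FALSE] %in% c("P", "A", "NN"))
  if (any(bad_snp) || any(bad_pav))
    stop_bad("illegal genotype codes for marker type")
  rownames(calls) <- individuals$id
  colnames(calls) <- markers$id
  structure(list(calls = calls, individuals = individuals, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals (%d F2) x %d markers (%d SNP, %d PAV)\n",
              nrow(x$calls), sum(x$individuals$role == "F2"), ncol(x$calls),
              sum(x$markers$type == "SNP"), sum(x$markers$type == "PAV")))
  invisible(x)
}

#' Read / write the genotype TSV dialect
#'
#' Rows are individuals (including the two parent rows), columns are markers.
#' The first three columns are `id`, `role` and `batch`; a `#type` line after
#' the header records each marker's type (SNP or PAV).
#'
#' @param path file path.
#' @return `read_genotypes` returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop_bad("genotype file too short: %s", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  typerow <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (typerow[1] != "#type") stop_bad("missing #type line in %s", path)
  marker_ids <- header[-(1:3)]
  types <- typerow[-(1:3)]
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t", fixed = TRUE))
  calls <- body[, -(1:3), drop = FALSE]
  genotype_matrix(
    calls,
    individuals = data.frame(id = body[, 1], role = body[, 2],
                             batch = ifelse(body[, 3] == ".", NA, body[, 3]),
                             stringsAsFactors = FALSE),
    markers = data.frame(id = marker_ids, type = types, stringsAsFactors = FALSE))
}

#' @rdname read_genotypes
#' @param x a [genotype_matrix()].
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  header <- paste(c("id", "role", "batch", x$markers$id), collapse = "\t")
  typerow <- paste(c("#type", ".", ".", x$markers$type), collapse = "\t")
  body <- apply(cbind(x$individuals$id, x$individuals$role,
                      ifelse(is.na(x$individuals$batch), ".", x$individuals$batch),
                      x$calls), 1, paste, collapse = "\t")
  writeLines(c(header, typerow, body), path)
  invisible(path)
}
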