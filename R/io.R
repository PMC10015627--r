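# Plain-text table I/O: tip trait tables, reproductive-mode tables, and
# CAFE-like gene-family count matrices.

#' Read a tip trait table (TSV)
#'
#' Expected layout: a `taxon` column (or first column) plus one numeric
#' column per trait.
#'
#' @param file path to a TSV file.
#' @return data.frame with a `taxon` column first.
#' @export
read_trait_table <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"taxon" %in% names(d)) names(d)[1L] <- "taxon"
  if (anyDuplicated(d$taxon)) stop("duplicate taxa in trait table")
  d
}

#' Read a reproductive-mode table (TSV: taxon, state)
#'
#' States are `selfer` / `outcrosser` (case-insensitive; 0/1 also accepted).
#'
#' @param file path to a TSV file.
#' @return named integer vector (0 = outcrosser, 1 = selfer) over taxa.
#' @export
read_regimes <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(d))) names(d)[1:2] <- c("taxon", "state")
  s <- tolower(trimws(as.character(d$state)))
  st <- ifelse(s %in% c("selfer", "1"), 1L,
               ifelse(s %in% c("outcrosser", "0"), 0L, NA_integer_))
  if (anyNA(st)) stop("unrecognized reproductive-mode state(s): ",
                      paste(unique(d$state[is.na(st)]), collapse = ", "))
  stats::setNames(st, d$taxon)
}

#' Read / write a gene-family count matrix (CAFE-like TSV)
#'
#' Layout: `Desc` TAB `FamilyID` TAB one integer column per taxon.
#'
#' @param file path.
#' @return integer matrix (families x taxa) with row names = family ids and
#'   attribute `desc`.
#' @export
read_families <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3L) stop("family table needs Desc, FamilyID and count columns")
  ids <- as.character(d[[2L]])
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) stop("family counts must be non-negative integers")
  rownames(m) <- ids
  attr(m, "desc") <- as.character(d[[1L]])
  m
}

#' @rdname read_families
#' @param counts family x taxon matrix.
#' @param desc optional description column.
#' @export
write_families <- function(counts, file, desc = NULL) {
  d <- data.frame(Desc = desc %||% attr(counts, "desc") %||%
                    rep("(null)", nrow(counts)),
                  FamilyID = rownames(counts) %||% paste0("fam", seq_len(nrow(counts))),
                  counts, check.names = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# deterministic TSV writer used by the pipeline (fixed significant digits so
# identical runs are byte-identical)
write_tsv_stable <- function(d, file, digits = 10) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = digits, format = "g"))
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
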