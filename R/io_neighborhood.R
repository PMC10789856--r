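# Gene-neighbourhood tables: ordered neighbour lists around a focal gene,
# the raw material of local-synteny comparisons. Offsets are signed gene
# ranks (... -2, -1, +1, +2 ...) relative to the focal gene, never base
# pairs; strand is ignored because only gene membership/order matters here.

#' Create a gene neighbourhood
#'
#' @param focal_id focal gene identifier.
#' @param chromosome chromosome / contig name.
#' @param symbols neighbour gene symbols.
#' @param offsets signed integer gene ranks, unique and non-zero.
#' @return object of class `gene_neighborhood` with neighbours sorted by
#'   ascending offset.
#' @export
gene_neighborhood <- function(focal_id, chromosome, symbols, offsets) {
  stopifnot(length(symbols) == length(offsets))
  if (!nzchar(focal_id)) stop("focal_id must be non-empty")
  offsets <- as.integer(offsets)
  if (anyNA(offsets)) stop("non-integer offset in neighbourhood of ", focal_id)
  if (any(offsets == 0L)) stop("offset 0 is not allowed (focal gene itself): ", focal_id)
  if (anyDuplicated(offsets)) {
    stop("duplicate offset(s) in neighbourhood of ", focal_id, ": ",
         paste(unique(offsets[duplicated(offsets)]), collapse = ", "))
  }
  if (any(!nzchar(symbols))) stop("empty neighbour symbol in neighbourhood of ", focal_id)
  ord <- order(offsets)
  structure(list(focal_id = focal_id,
                 chromosome = chromosome,
                 symbols = as.character(symbols)[ord],
                 offsets = offsets[ord]),
            class = "gene_neighborhood")
}

#' @export
print.gene_neighborhood <- function(x, ...) {
  cat(sprintf("neighbourhood of %s (%s): %d neighbour(s)\n",
              x$focal_id, x$chromosome, length(x$symbols)))
  invisible(x)
}

#' Read a neighbourhood table
#'
#' Tab-separated with header `focal_id`, `chromosome`, `symbol`, `offset`;
#' one row per neighbour gene. Rows are grouped by `focal_id` (order of first
#' appearance preserved).
#'
#' @param source path or the TSV text itself.
#' @return named list of [gene_neighborhood()] objects.
#' @export
read_neighborhood_table <- function(source) {
  lines <- read_source_lines(source, starter = "focal_id")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty neighbourhood table (missing header)")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("focal_id", "chromosome", "symbol", "offset")
  if (!all(need %in% header)) {
    stop("missing column(s): ", paste(setdiff(need, header), collapse = ", "))
  }
  col <- match(need, header)
  if (length(lines) == 1) return(structure(list(), names = character()))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) < max(col))
  if (length(bad)) stop("too few columns at data row ", bad[[1]])
  df <- data.frame(focal_id = vapply(rows, `[[`, "", col[[1]]),
                   chromosome = vapply(rows, `[[`, "", col[[2]]),
                   symbol = vapply(rows, `[[`, "", col[[3]]),
                   offset_raw = vapply(rows, `[[`, "", col[[4]]),
                   stringsAsFactors = FALSE)
  off <- suppressWarnings(as.integer(df$offset_raw))
  if (anyNA(off) | any(as.numeric(df$offset_raw) != off)) {
    stop("non-integer offset at data row ",
         which(is.na(off) | as.numeric(df$offset_raw) != off)[[1]])
  }
  df$offset <- off
  key <- paste(df$focal_id, df$offset, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (focal_id, offset) pair: (", d$focal_id, ", ", d$offset, ")")
  }
  ids <- unique(df$focal_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$focal_id == id, , drop = FALSE]
    if (length(unique(sub$chromosome)) > 1) {
      stop("inconsistent chromosome for focal gene ", id)
    }
    gene_neighborhood(id, sub$chromosome[[1]], sub$symbol, sub$offset)
  })
  names(out) <- ids
  out
}

#' Write a neighbourhood table
#'
#' @param neighborhoods list of [gene_neighborhood()] objects.
#' @param path optional output file.
#' @return the TSV text, invisibly when `path` is given.
#' @export
write_neighborhood_table <- function(neighborhoods, path = NULL) {
  lines <- "focal_id\tchromosome\tsymbol\toffset"
  for (nb in neighborhoods) {
    lines <- c(lines, sprintf("%s\t%s\t%s\t%d",
                              nb$focal_id, nb$chromosome, nb$symbols, nb$offsets))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
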