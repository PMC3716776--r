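#' Read a FASTA file
#'
#' Thin validating wrapper around the Biostrings readers. Sequences are
#' upcased on read (a message is emitted when any lowercase was present);
#' duplicate ids and empty sequences are hard errors. In DNA mode any
#' character outside A/C/G/T/N is a hard error naming the offending record.
#'
#' @param path FASTA file.
#' @param type \code{"dna"} or \code{"protein"}.
#' @return A \code{DNAStringSet} or \code{AAStringSet}.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0))
    stop("empty sequence for record ",
         ids[which(Biostrings::width(raw) == 0)[1]], " in ", path)
  chr <- as.character(raw)
  up <- toupper(chr)
  if (any(up != chr)) message("lowercase bases upcased on read: ", path)
  names(up) <- ids
  if (type == "dna") {
    bad <- grepl("[^ACGTN]", up)
    if (any(bad))
      stop("non-ACGTN characters in DNA record ", ids[which(bad)[1]])
    Biostrings::DNAStringSet(up)
  } else {
    Biostrings::AAStringSet(up)
  }
}

#' Write sequences as FASTA (80-column wrapped)
#' @param x named character vector, \code{DNAStringSet} or \code{AAStringSet}.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x))) stop("records must be named")
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# Read a TSV with '#' comments and a single header line; cols is a named
# character vector of required column -> type ("character"/"numeric"/
# "integer"/"logical"). Extra columns are kept as-is.
read_tsv_table <- function(path, cols) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "NA", check.names = FALSE)
  missing_cols <- setdiff(names(cols), names(d))
  if (length(missing_cols))
    stop(path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in names(cols)) {
    d[[nm]] <- switch(cols[[nm]],
                      character = as.character(d[[nm]]),
                      numeric = as.numeric(d[[nm]]),
                      integer = as.integer(d[[nm]]),
                      logical = as.logical(d[[nm]]),
                      d[[nm]])
  }
  d
}

write_tsv_table <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(format(d, trim = TRUE, scientific = FALSE,
                            justify = "none"),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read contigs with coverage and marker annotations
#'
#' @param fasta contig FASTA (DNA).
#' @param meta TSV with columns \code{contig_id}, \code{coverage} and an
#'   optional \code{markers} column of semicolon-separated
#'   \code{"COGid:taxon"} entries.
#' @return A [contig_set()].
#' @export
read_contigs <- function(fasta, meta) {
  seqs <- read_fasta(fasta, "dna")
  m <- read_tsv_table(meta, c(contig_id = "character", coverage = "numeric"))
  missing_ids <- setdiff(names(seqs), m$contig_id)
  if (length(missing_ids))
    stop("no coverage for contig(s): ", paste(missing_ids, collapse = ", "))
  m <- m[match(names(seqs), m$contig_id), ]
  markers <- NULL
  if ("markers" %in% names(m)) {
    has <- !is.na(m$markers) & nzchar(m$markers)
    if (any(has)) {
      markers <- lapply(strsplit(m$markers[has], ";", fixed = TRUE),
                        function(v) {
                          parts <- strsplit(v, ":", fixed = TRUE)
                          data.frame(cog = vapply(parts, `[`, "", 1L),
                                     taxon = vapply(parts, `[`, "", 2L),
                                     stringsAsFactors = FALSE)
                        })
      names(markers) <- m$contig_id[has]
    }
  }
  contig_set(seqs, m$coverage, markers)
}

#' Write a contig set as FASTA plus metadata TSV
#' @param contigs a [contig_set()].
#' @param fasta,meta output paths.
#' @export
write_contigs <- function(contigs, fasta, meta) {
  write_fasta(contigs$sequences, fasta)
  mk <- vapply(contigs$markers, function(m) {
    if (is.null(m) || nrow(m) == 0) return(NA_character_)
    paste(paste0(m$cog, ":", m$taxon), collapse = ";")
  }, "")
  d <- data.frame(contig_id = contigs$meta$id,
                  length = contigs$meta$length,
                  coverage = contigs$meta$coverage,
                  gc = round(contigs$meta$gc, 6),
                  markers = mk, stringsAsFactors = FALSE)
  write_tsv_table(d, meta, "contig metadata; markers as COGid:taxon;...")
  invisible(NULL)
}

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults: composition
#' score cutoff 0.01 and 120% second-best margin for the vetoed assignment
#' rounds, 1000 bp minimum contig length, chain order 3, 95% dereplication
#' identity, top-33% rollup, data-relative censoring floor, alpha 0.05 and
#' enrichment FDR 0.10.
#'
#' @param ... overrides of the default fields.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(score_max = 0.01, margin = 1.2, min_len = 1000, order = 3,
              identity = 0.95, top_fraction = 0.33, floor = "auto",
              alpha = 0.05, fdr = 0.10, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a flat key=value config file
#' @param path config file: one \code{key = value} per line, '#' comments.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- vapply(config, function(v)
    format(v, scientific = FALSE, trim = TRUE), "")
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}
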