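# Amino-acid alignments and partition schemes.
#
# An alignment is a plain character matrix (rows = taxa, columns = sites,
# uppercase residues; gaps and ambiguity codes are missing data). Partition
# schemes use 0-based half-open site ranges internally; the text format read
# from disk uses the conventional 1-based inclusive ranges.

#' Construct / validate an amino-acid alignment
#'
#' @param x A character matrix (rows = taxa with rownames, columns = sites)
#'   or a named list of equal-length residue strings.
#' @return A character matrix with uppercase residues, class
#'   `"aa_alignment"` prepended.
#' @export
aa_alignment <- function(x) {
  if (is.list(x)) {
    lens <- vapply(x, nchar, integer(1))
    if (length(unique(lens)) > 1L) stop("sequences have unequal lengths")
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x))) stop("alignment must have taxon rownames")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon in alignment")
  x[] <- toupper(x)
  ok <- x %in% c(AA_ALPHABET, AA_MISSING)
  if (!all(ok)) {
    stop("invalid residue code(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  }
  class(x) <- c("aa_alignment", class(x))
  x
}

#' Read a FASTA amino-acid alignment
#'
#' @param path FASTA file path.
#' @return An `"aa_alignment"` matrix.
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  aa_alignment(stats::setNames(as.list(seqs), ids))
}

#' Write an alignment as FASTA
#'
#' @param aln An `"aa_alignment"`.
#' @param path Output file.
#' @param width Residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(aln)) {
    writeLines(paste0(">", tx), con)
    s <- paste(aln[tx, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a partition scheme
#'
#' @param names Character vector of partition names.
#' @param starts,ends Integer vectors of 0-based half-open site ranges
#'   `[start, end)`; ranges must be disjoint and, for likelihood use, cover
#'   the alignment.
#' @param models A single `"subst_model"` recycled to all partitions, or a
#'   list of one model per partition.
#' @return An object of class `"partition_scheme"`.
#' @export
partition_scheme <- function(names, starts, ends, models) {
  stopifnot(length(names) == length(starts), length(starts) == length(ends))
  if (inherits(models, "subst_model")) {
    models <- rep(list(models), length(names))
  }
  stopifnot(length(models) == length(names))
  if (any(ends <= starts)) stop("empty partition range")
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  if (any(s[-1] < e[-length(e)])) stop("overlapping partition ranges")
  structure(list(name = as.character(names), start = as.integer(starts),
                 end = as.integer(ends), models = models),
            class = "partition_scheme")
}

#' Number of partitions
#' @param scheme A `"partition_scheme"`.
#' @return Integer.
#' @export
n_partitions <- function(scheme) length(scheme$name)

# Check that a scheme exactly covers an alignment of `len` sites.
check_scheme_covers <- function(scheme, len) {
  ord <- order(scheme$start)
  s <- scheme$start[ord]; e <- scheme$end[ord]
  if (s[1] != 0L || e[length(e)] != len || any(s[-1] != e[-length(e)])) {
    stop("partition scheme does not cover the alignment (0..", len, ")")
  }
  invisible(TRUE)
}

#' Parse a partition map file
#'
#' Plain-text lines of the form `name = 12-340` with 1-based inclusive site
#' ranges (the conventional layout), converted to the package's 0-based
#' half-open ranges.
#'
#' @param path Partition map file.
#' @param models Model(s) to attach, as in [partition_scheme()].
#' @return A `"partition_scheme"`.
#' @export
read_partition_map <- function(path, models) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)$", lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("unparseable partition line: ", lines[bad][1])
  nm <- vapply(m, `[`, character(1), 2)
  from <- as.integer(vapply(m, `[`, character(1), 3))
  to <- as.integer(vapply(m, `[`, character(1), 4))
  partition_scheme(nm, from - 1L, to, models)
}

#' Concatenate alignments into a partitioned super-alignment
#'
#' Appends blocks in input order over the union of their taxa; a taxon
#' absent from a block is filled with gaps there. Records the partition
#' ranges (0-based half-open).
#'
#' @param alignments Non-empty named list of `"aa_alignment"` matrices.
#' @param models Model(s) to attach to the partitions, as in
#'   [partition_scheme()].
#' @return A list with `alignment` (the concatenated `"aa_alignment"`) and
#'   `scheme` (the `"partition_scheme"`).
#' @export
concatenate_alignments <- function(alignments, models) {
  if (!length(alignments)) stop("no alignment blocks supplied")
  if (is.null(names(alignments))) {
    names(alignments) <- paste0("part", seq_along(alignments))
  }
  taxa <- sort(unique(unlist(lapply(alignments, rownames))))
  lens <- vapply(alignments, ncol, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  big <- matrix("-", length(taxa), sum(lens),
                dimnames = list(taxa, NULL))
  for (i in seq_along(alignments)) {
    blk <- alignments[[i]]
    big[rownames(blk), (starts[i] + 1L):ends[i]] <- blk
  }
  list(alignment = aa_alignment(big),
       scheme = partition_scheme(names(alignments), starts, ends, models))
}
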