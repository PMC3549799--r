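#' Construct a table of sequenced reads
#'
#' The read container used throughout the pipeline: one row per read with
#' identifier, bases, per-base phred scores and a multiplicity count
#' (number of identical reads collapsed into the row; 1 before collapsing).
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of DNA strings over `{A,C,G,T,N}`.
#' @param quals list of integer vectors of phred scores, one per read, each
#'   the same length as its read.
#' @param multiplicity integer vector (recycled) of collapse counts, >= 1.
#' @return a `data.frame` with columns `read_id`, `bases`, `quals`
#'   (list column), `multiplicity`.
#' @export
sequenced_reads <- function(read_id = character(), bases = character(),
                            quals = list(), multiplicity = 1L) {
  read_id <- as.character(read_id)
  bases <- toupper(as.character(bases))
  if (length(read_id) != length(bases) || length(bases) != length(quals))
    stop("read_id, bases and quals must have equal length")
  multiplicity <- as.integer(rep_len(multiplicity, length(bases)))
  quals <- lapply(quals, as.integer)
  bad <- which(nchar(bases) != lengths(quals))
  if (length(bad))
    stop("read(s) ", paste(head(bad, 5), collapse = ", "),
         ": length of bases and quality scores differ")
  if (any(multiplicity < 1L)) stop("multiplicity must be >= 1")
  df <- data.frame(read_id = read_id, bases = bases,
                   multiplicity = multiplicity, stringsAsFactors = FALSE)
  df$quals <- quals
  df[, c("read_id", "bases", "quals", "multiplicity")]
}

#' Read a 4-line FASTQ file
#'
#' Plain 4-line-per-record FASTQ parser. Qualities are decoded as
#' `ASCII - phred_offset`; malformed records are reported with their
#' 1-based record index.
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @param phred_offset 33 (Sanger, default) or 64 (legacy Illumina).
#' @return a reads table as from [sequenced_reads()].
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!phred_offset %in% c(33L, 64L)) stop("phred_offset must be 33 or 64")
  lines <- readLines(path)
  if (length(lines) == 0L) return(sequenced_reads())
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ record ", length(lines) %/% 4L + 1L,
         " in ", path, ": truncated record")
  n <- length(lines) %/% 4L
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": missing '+' separator line")
  bad <- which(nchar(seqs) != nchar(qstr))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": sequence and quality lengths differ")
  quals <- lapply(qstr, function(q) utf8ToInt(q) - as.integer(phred_offset))
  neg <- which(vapply(quals, function(q) any(q < 0L), logical(1)))
  if (length(neg))
    stop("malformed FASTQ record ", neg[1],
         ": negative phred score (wrong phred_offset?)")
  sequenced_reads(sub("^@", "", ids), toupper(seqs), quals)
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads reads table (see [sequenced_reads()]).
#' @param path output path.
#' @param phred_offset quality encoding offset, 33 or 64.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, phred_offset = 33L) {
  qstr <- vapply(reads$quals,
                 function(q) intToUtf8(q + as.integer(phred_offset)),
                 character(1))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
    out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
    out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = nrow(reads))] <- qstr
  }
  writeLines(out, path)
  invisible(path)
}

# shared FASTA reader: uppercase, U->T, duplicate-id check
read_fasta_table <- function(path, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read 3'UTR reference sequences from FASTA
#'
#' Sequences are uppercased and stored as DNA (U -> T). An optional
#' conservation table flags each UTR as conserved or not.
#'
#' @param path FASTA file of 3'UTR sequences; record ids must be unique.
#' @param conservation optional conservation table
#'   (see [read_conservation_tsv()]) or path to one.
#' @return `data.frame` with columns `utr_id`, `sequence`, `conserved`
#'   (logical, `NA` when unknown).
#' @export
read_utr_fasta <- function(path, conservation = NULL) {
  tab <- read_fasta_table(path, "UTR")
  utrs <- data.frame(utr_id = tab$id, sequence = tab$sequence,
                     conserved = NA, stringsAsFactors = FALSE)
  if (!is.null(conservation)) {
    if (is.character(conservation)) conservation <- read_conservation_tsv(conservation)
    utrs$conserved <- conservation$conserved[match(utrs$utr_id, conservation$utr_id)]
  }
  utrs
}

#' Read mature miRNA sequences from FASTA
#'
#' miRNA FASTA may be RNA (U) or DNA (T); sequences are stored as DNA.
#' Every miRNA must be at least 8 nt long so that positions 1-8 (the seed
#' and the m8 anchor) exist.
#'
#' @param path FASTA file of mature miRNA sequences, 5'->3'.
#' @param expression optional expression table (see [read_expression_tsv()])
#'   or path to one.
#' @return `data.frame` with columns `mirna_id`, `sequence`, `expression`.
#' @export
read_mirna_fasta <- function(path, expression = NULL) {
  tab <- read_fasta_table(path, "miRNA")
  short <- tab$id[nchar(tab$sequence) < 8L]
  if (length(short))
    stop("miRNA(s) shorter than 8 nt: ", paste(short, collapse = ", "))
  mir <- data.frame(mirna_id = tab$id, sequence = tab$sequence,
                    expression = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    if (is.character(expression)) expression <- read_expression_tsv(expression)
    mir$expression <- expression$expression[match(mir$mirna_id, expression$mirna_id)]
  }
  mir
}

# two-column TSV reader tolerating an optional header line
read_two_col_tsv <- function(path, col1, col2) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) && identical(tolower(tab[1, 1]), col1)) tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2L) stop(path, ": expected two tab-separated columns")
  names(tab)[1:2] <- c(col1, col2)
  rownames(tab) <- NULL
  tab[, 1:2]
}

#' Read a miRNA expression TSV (`mirna_id<TAB>expression`)
#' @param path path to the TSV (optional header).
#' @return `data.frame` with columns `mirna_id`, `expression` (numeric).
#' @export
read_expression_tsv <- function(path) {
  tab <- read_two_col_tsv(path, "mirna_id", "expression")
  tab$expression <- as.numeric(tab$expression)
  tab
}

#' Read a validated-MTI TSV (`mirna_id<TAB>utr_id`)
#'
#' Each row records an experimentally supported miRNA-target pair
#' (miRNA, gene/UTR), used to put validated interactions on top of the
#' ranking.
#' @param path path to the TSV (optional header).
#' @return `data.frame` with columns `mirna_id`, `utr_id`.
#' @export
read_validated_tsv <- function(path) read_two_col_tsv(path, "mirna_id", "utr_id")

#' Read a UTR conservation TSV (`utr_id<TAB>0/1`)
#' @param path path to the TSV (optional header).
#' @return `data.frame` with columns `utr_id`, `conserved` (logical).
#' @export
read_conservation_tsv <- function(path) {
  tab <- read_two_col_tsv(path, "utr_id", "conserved")
  tab$conserved <- as.integer(tab$conserved) > 0L
  tab
}

#' Write the ranked target-site report
#'
#' One row per target site, in rank order, with 1-based inclusive UTR
#' coordinates (internal coordinates are 0-based half-open).
#'
#' @param sites ranked site table from [rank_mtis()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  cols <- c("utr_id", "mirna_id", "site_start", "site_end", "seed_match_type",
            "cluster_id", "read_support", "conversion_read_fraction",
            "validated_flag", "expression", "rank")
  if (is.null(sites) || nrow(sites) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(
    utr_id = sites$utr_id,
    mirna_id = sites$mirna_id,
    site_start = sites$site_start + 1L,   # 0-based half-open -> 1-based inclusive
    site_end = sites$site_end,
    seed_match_type = sites$seed_match_type,
    cluster_id = sites$cluster_id,
    read_support = sites$read_support,
    conversion_read_fraction = sites$conversion_read_fraction,
    validated_flag = as.integer(sites$validated),
    expression = sites$expression,
    rank = sites$rank,
    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a FASTA file from an id/sequence table
#' @param ids,seqs character vectors of equal length.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}
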