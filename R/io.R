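# Standard-format I/O.  Internal coordinates are 0-based half-open
# everywhere; GFF3's 1-based closed convention is converted only here.

#' Write a marker genome to FASTA + GFF3
#'
#' @param genome A `marker_genome` with sequence.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default the taxon id).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, dir, prefix = genome$taxon_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  write_fasta(genome, fa)
  write_gff3(genome, gff)
  invisible(c(fasta = fa, gff3 = gff))
}

#' @rdname write_genome
#' @param path Output FASTA path.
#' @export
write_fasta <- function(genome, path) {
  seqs <- lapply(genome$chromosomes, function(ch) {
    if (is.null(ch$sequence)) stop("chromosome ", ch$name, " has no sequence")
    ch$sequence
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- chrom_names(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write marker annotation as GFF3
#'
#' Features are emitted as `gene` records; internal 0-based half-open
#' coordinates become 1-based closed at this boundary only.
#'
#' @param genome A `marker_genome`.
#' @param path Output path.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in genome$chromosomes)
    writeLines(sprintf("##sequence-region %s 1 %d", ch$name, ch$length), con)
  for (ch in genome$chromosomes) {
    m <- ch$markers
    if (!nrow(m)) next
    writeLines(sprintf("%s\tparacentric\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       ch$name, m$start + 1L, m$end, m$strand, m$id), con)
  }
  invisible(path)
}

#' Read a marker genome from FASTA + GFF3
#'
#' @param fasta,gff3 Input paths.
#' @param taxon_id Taxon label for the resulting genome.
#' @return A `marker_genome`.
#' @export
read_genome <- function(fasta, gff3, taxon_id) {
  dss <- Biostrings::readDNAStringSet(fasta)
  names(dss) <- sub("\\s.*$", "", names(dss))
  lens <- setNames(Biostrings::width(dss), names(dss))
  feats <- read_gff3(gff3, seq_lengths = lens)
  chroms <- lapply(names(dss), function(nm) {
    m <- feats[feats$chrom == nm, c("id", "start", "end", "strand")]
    m <- m[order(m$start), , drop = FALSE]
    rownames(m) <- NULL
    list(name = nm, length = unname(lens[[nm]]), markers = m,
         sequence = as.character(dss[[nm]]))
  })
  names(chroms) <- names(dss)
  marker_genome(taxon_id, chroms)
}

#' Read a GFF3 marker annotation
#'
#' Returns 0-based half-open coordinates.  Malformed lines raise an error
#' with the offending line number; coordinates beyond the declared
#' sequence lengths (when supplied) are rejected.
#'
#' @param path GFF3 path.
#' @param seq_lengths Optional named vector of chromosome lengths for
#'   bounds checking.
#' @return data.frame with `chrom`, `id`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path, seq_lengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, " in ", path, ": expected 9 fields, got ",
           length(f))
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1)
      stop("malformed GFF3 line ", i, " in ", path, ": bad coordinates")
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9L])
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1L], id = id, start = start1 - 1L, end = end1,
      strand = f[7L], stringsAsFactors = FALSE)
  }
  d <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), id = character(), start = integer(),
                  end = integer(), strand = character(),
                  stringsAsFactors = FALSE)
  if (!is.null(seq_lengths) && nrow(d)) {
    for (j in seq_len(nrow(d))) {
      L <- seq_lengths[[d$chrom[j]]]
      if (!is.null(L) && !is.na(L) && d$end[j] > L)
        stop("GFF3 feature '", d$id[j], "' ends at ", d$end[j],
             ", beyond ", d$chrom[j], " length ", L)
    }
  }
  d
}

#' Write repeat annotation as BED
#'
#' @param bed data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (0-based half-open, as BED requires).
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  nm <- if ("name" %in% names(bed)) bed$name else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", bed$chrom, bed$start, bed$end, nm),
             path)
  invisible(path)
}

#' Read a BED repeat annotation
#'
#' @param path BED path.
#' @param seq_lengths Optional named vector of chromosome lengths; records
#'   extending beyond them are rejected with an informative error.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path, seq_lengths = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, " in ", path, ": expected >= 3 fields")
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start)
      stop("malformed BED line ", i, " in ", path, ": bad coordinates")
    if (!is.null(seq_lengths)) {
      L <- seq_lengths[[f[1L]]]
      if (!is.null(L) && !is.na(L) && end > L)
        stop("BED line ", i, " in ", path, ": end ", end,
             " beyond chromosome ", f[1L], " length ", L)
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1L], start = start, end = end,
      name = if (length(f) >= 4L) f[4L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  d <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  name = character(), stringsAsFactors = FALSE)
  d
}

#' Write a result table as TSV with provenance metadata
#'
#' Metadata (seed, config hash, package version) is written as `#`-prefixed
#' header lines so that reruns are auditable and byte-identical.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @export
write_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, as.character(meta[[nm]])), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return data.frame; metadata lines are returned in attribute `"meta"`.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  d <- read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  sep = "\t", stringsAsFactors = FALSE)
  meta <- list()
  for (ln in metal) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  attr(d, "meta") <- meta
  d
}

#' Write the ground-truth event table
#'
#' TSV with header
#' `event_id chrom left_bp right_bp mechanism offset_left offset_right branch state`.
#'
#' @param truth A `truth_table` from [evolve_subgroup()].
#' @param path Output path.
#' @export
write_truth_table <- function(truth, path) {
  write_tsv(truth$events, path, meta = list(seed = truth$seed))
}
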