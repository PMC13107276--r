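#' Plastome records
#'
#' A `plastome_record` holds one circular plastid genome linearised at the
#' conventional large single-copy (LSC) start: the sequence, the taxon and
#' trophic class (AP = obligate autotroph, CP = carnivore, MP =
#' mycoheterotroph, HP = holoparasite), and a feature table. Coordinates are
#' 1-based inclusive throughout; features that wrap the circular origin are
#' split into two rows sharing a `wrap` flag.
#'
#' @param id Accession-like identifier.
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param taxon Taxon name.
#' @param trophic_class One of `"AP"`, `"CP"`, `"MP"`, `"HP"` or `NA`.
#' @param features Data frame with columns `name`, `category` (one of
#'   `PS`, `HK`, `ndh`, `tRNA`, `rRNA`), `strand` (`"+"`/`"-"`), `start`,
#'   `end`, `exon`, `status`, `wrap`.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(id, sequence, taxon = id, trophic_class = NA,
                            features = empty_features()) {
  sequence <- toupper(sequence)
  check_dna(sequence, sprintf("plastome '%s'", id))
  if (nchar(sequence) == 0L) stop("empty sequence for plastome '", id, "'")
  features <- as.data.frame(features)
  need <- c("name", "category", "strand", "start", "end", "exon", "status", "wrap")
  miss <- setdiff(need, names(features))
  for (m in miss) {
    features[[m]] <- switch(m, exon = 1L, status = "unknown", wrap = FALSE,
                            category = "HK", strand = "+", stop("feature table lacks column ", m))
  }
  features <- features[, need, drop = FALSE]
  if (nrow(features) > 0) {
    bad <- features$start < 1 | features$end > nchar(sequence) |
      features$start > features$end
    if (any(bad)) {
      stop("feature intervals outside [1, genome length]: ",
           paste(features$name[bad], collapse = ", "))
    }
  }
  structure(list(id = id, taxon = taxon,
                 trophic_class = if (is.na(trophic_class)) NA_character_ else
                   match.arg(trophic_class, c("AP", "CP", "MP", "HP")),
                 sequence = sequence, features = features),
            class = "plastome_record")
}

empty_features <- function() {
  data.frame(name = character(0), category = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             exon = integer(0), status = character(0), wrap = logical(0))
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("plastome_record %s (%s, %s): %s bp, %d features\n",
              x$id, x$taxon, ifelse(is.na(x$trophic_class), "?", x$trophic_class),
              format(nchar(x$sequence), big.mark = ","), nrow(x$features)))
  invisible(x)
}

#' Genome length of a plastome record
#' @param record A `plastome_record`.
#' @return Length in bases.
#' @export
genome_length <- function(record) nchar(record$sequence)

#' Read a plastome from FASTA or GenBank
#'
#' FASTA yields a record with an empty feature table; GenBank flat files have
#' their `CDS`, `gene`, `tRNA` and `rRNA` features mapped to the feature
#' table (1-based coordinates kept as-is, `complement`/`join` locations
#' resolved into per-exon rows).
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"` (default guessed from extension).
#' @param trophic_class Optional trophic class to attach.
#' @return A [plastome_record()].
#' @export
read_plastome <- function(path, format = c("auto", "fasta", "genbank"),
                          trophic_class = NA) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L) stop("no sequences in FASTA file ", path)
    if (Biostrings::width(ss)[1] == 0L)
      stop("empty sequence under FASTA header in ", path)
    id <- sub("\\s.*$", "", names(ss)[1])
    plastome_record(id, as.character(ss[[1]]), taxon = names(ss)[1],
                    trophic_class = trophic_class)
  } else {
    parse_genbank(path, trophic_class)
  }
}

## Minimal GenBank flat-file parser: LOCUS id, ORGANISM, FEATURES (gene/CDS/
## tRNA/rRNA with join/complement locations) and ORIGIN sequence.
parse_genbank <- function(path, trophic_class = NA) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L) stop("malformed GenBank file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus[1]])), "\\s+")[[1]][1]
  org <- grep("^\\s+ORGANISM", lines)
  taxon <- if (length(org) > 0) trimws(sub("^\\s+ORGANISM", "", lines[org[1]])) else id
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L)
    stop("malformed GenBank file (no ORIGIN section): ", path,
         " near line ", length(lines))
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    stop("GenBank file has an empty ORIGIN sequence: ", path)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart) > 0) {
    fend <- ostart[1] - 1L
    flines <- lines[(fstart[1] + 1L):fend]
    key_idx <- grep("^\\s{5}\\S", flines)
    for (ki in seq_along(key_idx)) {
      i0 <- key_idx[ki]
      i1 <- if (ki < length(key_idx)) key_idx[ki + 1L] - 1L else length(flines)
      block <- flines[i0:i1]
      parts <- strsplit(trimws(block[1]), "\\s+")[[1]]
      key <- parts[1]
      if (!key %in% c("CDS", "gene", "tRNA", "rRNA")) next
      if (key == "gene" && any(grepl("^\\s{5}(CDS|tRNA|rRNA)", flines))) {
        # keep only the typed child features when present; gene lines
        # duplicate them
        next
      }
      loc <- paste0(parts[-1], collapse = "")
      j <- 2L
      while (j <= length(block) && !grepl("^\\s{21}/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      quals <- if (j <= length(block))
        paste(block[j:length(block)], collapse = " ") else ""
      gene <- regmatches(quals, regexpr('/gene="[^"]*"', quals))
      name <- if (length(gene) == 1) sub('/gene="([^"]*)"', "\\1", gene) else key
      pl <- parse_gb_location(loc, line_hint = fstart[1] + i0)
      cat_guess <- switch(key, tRNA = "tRNA", rRNA = "rRNA",
                          if (grepl("^ndh", name)) "ndh" else "HK")
      feats <- rbind(feats, data.frame(
        name = name, category = cat_guess, strand = pl$strand,
        start = pl$start, end = pl$end, exon = seq_along(pl$start),
        status = "unknown", wrap = FALSE))
    }
  }
  plastome_record(id, sequence, taxon = taxon, trophic_class = trophic_class,
                  features = feats)
}

parse_gb_location <- function(loc, line_hint = NA) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", parts))
  single <- regmatches(parts, regexec("^(\\d+)$", parts))
  starts <- ends <- integer(0)
  for (k in seq_along(parts)) {
    if (length(m[[k]]) == 3) {
      starts <- c(starts, as.integer(m[[k]][2]))
      ends <- c(ends, as.integer(m[[k]][3]))
    } else if (length(single[[k]]) == 2) {
      starts <- c(starts, as.integer(single[[k]][2]))
      ends <- c(ends, as.integer(single[[k]][2]))
    } else {
      stop("cannot parse GenBank location '", loc, "' near line ", line_hint)
    }
  }
  list(start = starts, end = ends, strand = strand)
}

#' Write a plastome record to FASTA (and optionally GFF3)
#'
#' @param record A [plastome_record()].
#' @param fasta Path for the FASTA output.
#' @param gff Optional path for a GFF3 feature file.
#' @return Invisibly, the record.
#' @export
write_plastome <- function(record, fasta, gff = NULL) {
  ss <- Biostrings::DNAStringSet(record$sequence)
  names(ss) <- record$id
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(gff)) write_features_gff(record, gff)
  invisible(record)
}

## GFF3 feature export via rtracklayer.
write_features_gff <- function(record, path) {
  f <- record$features
  if (nrow(f) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(NULL))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  gr$type <- ifelse(f$category == "tRNA", "tRNA",
                    ifelse(f$category == "rRNA", "rRNA", "CDS"))
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  gr$ID <- paste0(f$name, ".", f$exon)
  gr$Name <- f$name
  gr$gene <- f$name
  gr$category <- f$category
  gr$status <- f$status
  gr$wrap <- f$wrap
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}

#' Read a GFF3 feature table into the plastome feature format
#'
#' @param path GFF3 file.
#' @return Feature data frame as used by [plastome_record()].
#' @export
read_features_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_features())
  md <- S4Vectors::mcols(gr)
  name <- if ("gene" %in% names(md)) as.character(md$gene) else
    if ("Name" %in% names(md)) as.character(md$Name) else
      as.character(md$ID)
  category <- if ("category" %in% names(md)) as.character(md$category) else
    ifelse(as.character(md$type) == "tRNA", "tRNA",
           ifelse(as.character(md$type) == "rRNA", "rRNA",
                  ifelse(grepl("^ndh", name), "ndh", "HK")))
  status <- if ("status" %in% names(md)) as.character(md$status) else "unknown"
  wrap <- if ("wrap" %in% names(md)) as.logical(md$wrap) else FALSE
  exon <- stats::ave(seq_along(name), name, FUN = seq_along)
  data.frame(name = name, category = category,
             strand = as.character(BiocGenerics::strand(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             exon = as.integer(exon), status = status, wrap = wrap)
}
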