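#' Construct and validate a genome record
#'
#' A genome record bundles one lineage's chromosome sequence with its
#' strand-aware CDS annotation.  All coordinates are 1-based inclusive, the
#' GFF3 dialect, at every interface of this package.
#'
#' @param genome_id Text label for the lineage (FASTA header word).
#' @param sequence Nucleotide string over A/C/G/T (uppercased on construction).
#' @param features Data frame of CDS features with columns `feature_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and optionally `product`.
#' @return An object of class `genome_record`: a list with elements
#'   `genome_id`, `sequence` and `features` (a tibble).
#' @examples
#' genome_record("toy", "ATGAAATAAT",
#'               data.frame(feature_id = "cds1", start = 2, end = 7,
#'                          strand = "+"))
#' @export
genome_record <- function(genome_id, sequence, features = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1,
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) abort("genome sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) {
    abort("genome sequence contains non-ACGT characters; see `ambiguity` in read_genome()")
  }
  if (is.null(features)) {
    features <- tibble(feature_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       product = character())
  }
  features <- as_tibble(features)
  if (!"product" %in% names(features)) features$product <- NA_character_
  features <- features[, c("feature_id", "start", "end", "strand", "product")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  len <- nchar(sequence)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (is.na(f$start) || is.na(f$end) || f$start < 1 || f$start > f$end) {
      abort(sprintf("feature '%s' has an invalid interval", f$feature_id))
    }
    if (f$end > len) {
      abort(sprintf("feature out of bounds: '%s' ends at %d on a %d-bp genome",
                    f$feature_id, f$end, len))
    }
    if (!f$strand %in% c("+", "-")) {
      abort(sprintf("feature '%s' has strand '%s'; must be '+' or '-'",
                    f$feature_id, f$strand))
    }
  }
  structure(list(genome_id = genome_id, sequence = sequence,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %d CDS features\n",
              x$genome_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Read a genome from FASTA + GFF3
#'
#' Loads the first FASTA record and its CDS features.  Lowercase input is
#' uppercased; ambiguity codes are rejected by default or masked to `A`
#' (matching the AT-rich composition prior of reduced endosymbiont genomes)
#' with a warning.
#'
#' @param fasta_path Path to a FASTA file; the first word of the header is the
#'   genome id.
#' @param gff_path Path to a GFF3 file; features of type `CDS` are kept and
#'   the `ID` attribute becomes `feature_id`.
#' @param ambiguity `"error"` (default) to reject non-ACGT characters,
#'   `"mask"` to replace them with `A`.
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta_path, gff_path, ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  for (p in c(fasta_path, gff_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) abort(sprintf("no sequences in %s", fasta_path))
  genome_id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  sequence <- toupper(as.character(seqs[[1]]))
  if (grepl("[^ACGT]", sequence)) {
    if (ambiguity == "mask") {
      n_bad <- nchar(gsub("[ACGT]", "", sequence))
      warn(sprintf("masking %d ambiguous bases to 'A' in %s", n_bad, genome_id))
      sequence <- gsub("[^ACGT]", "A", sequence)
    } else {
      abort(sprintf("genome %s contains ambiguity codes (use ambiguity = \"mask\")",
                    genome_id))
    }
  }
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[as.character(gff$type) == "CDS"]
  if (length(gff) > 0) {
    seqids <- unique(as.character(GenomicRanges::seqnames(gff)))
    if (!all(seqids == genome_id)) {
      abort(sprintf("GFF3 seqid (%s) does not match FASTA header (%s)",
                    paste(seqids, collapse = ","), genome_id))
    }
  }
  ids <- if (!is.null(gff$ID)) as.character(gff$ID) else
    paste0("cds_", seq_along(gff))
  product <- if (!is.null(gff$product)) as.character(gff$product) else
    NA_character_
  features <- tibble(
    feature_id = ids,
    start = BiocGenerics::start(gff),
    end = BiocGenerics::end(gff),
    strand = as.character(BiocGenerics::strand(gff)),
    product = product
  )
  genome_record(genome_id, sequence, features)
}

#' Write a genome record to FASTA + GFF3
#'
#' @param genome A [genome_record()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$genome_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  f <- genome$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$genome_id,
                     nchar(genome$sequence)))
  if (nrow(f) > 0) {
    attrs <- sprintf("ID=%s", f$feature_id)
    has_prod <- !is.na(f$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", f$product[has_prod])
    lines <- c(lines, sprintf("%s\tsrnacons\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              genome$genome_id, f$start, f$end, f$strand, attrs))
  }
  writeLines(lines, gff_path)
  invisible(genome)
}

# Fixed sRNA-table column order; expr_* sample columns follow.
SRNA_COLS <- c("srna_id", "genome_id", "start", "end", "strand", "category")

#' Read / write an sRNA coordinate table
#'
#' TSV with fixed leading columns `srna_id`, `genome_id`, `start`, `end`,
#' `strand`, `category` and any number of `expr_*` per-sample mean-expression
#' columns.  `category` is one of `antisense`, `utr`, `intergenic`, or
#' `unset` for tables that have not been classified yet.  Tables round-trip
#' losslessly: `read_srna_table(write_srna_table(x, p))` equals `x`.
#'
#' Native output of bacterial transcript callers is not parsed verbatim;
#' converting it is a two-line recipe.  For a Rockhopper-style
#' `*_transcripts.txt` with `Transcription Start`/`Transcription Stop`
#' columns:
#' ```r
#' raw <- readr::read_tsv("transcripts.txt")
#' tbl <- dplyr::transmute(raw,
#'   srna_id = paste0("srna_", dplyr::row_number()), genome_id = "my_genome",
#'   start = pmin(`Transcription Start`, `Transcription Stop`),
#'   end = pmax(`Transcription Start`, `Transcription Stop`),
#'   strand = ifelse(`Transcription Start` <= `Transcription Stop`, "+", "-"),
#'   category = "unset")
#' ```
#'
#' @param path TSV file path.
#' @return A tibble (the sRNA table).
#' @export
read_srna_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    srna_id = readr::col_character(),
    genome_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    strand = readr::col_character(),
    category = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(SRNA_COLS, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("sRNA table %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  validate_srna_table(tbl, path)
  tbl
}

validate_srna_table <- function(tbl, path = "<srna table>") {
  bad <- which(is.na(tbl$start) | is.na(tbl$end) | tbl$start < 1 |
                 tbl$start > tbl$end)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval (start=%s end=%s)",
                  path, bad[1] + 1L, tbl$start[bad[1]], tbl$end[bad[1]]))
  }
  bad <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: strand must be '+' or '-'", path, bad[1] + 1L))
  }
  bad <- which(!tbl$category %in% c("antisense", "utr", "intergenic", "unset"))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: unknown category '%s'", path, bad[1] + 1L,
                  tbl$category[bad[1]]))
  }
  invisible(tbl)
}

#' @rdname read_srna_table
#' @param tbl sRNA table (tibble) to write.
#' @export
write_srna_table <- function(tbl, path) {
  expr_cols <- grep("^expr_", names(tbl), value = TRUE)
  tbl <- tbl[, c(SRNA_COLS, expr_cols)]
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Parse a dot-bracket secondary structure
#'
#' Stack-matching of `(`/`)` with `.` for unpaired positions.  The derived
#' pair table lists each basepair once as `(i, j)` with `i < j`.
#'
#' @param text Dot-bracket string over `(`, `)`, `.`.
#' @return An object of class `dot_bracket`: list with `structure`, `length`
#'   and `pairs` (tibble with columns `i`, `j`).
#' @examples
#' parse_dot_bracket("((..))")$pairs
#' @export
parse_dot_bracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- str_bases(text)
  illegal <- setdiff(unique(chars), c("(", ")", "."))
  if (length(illegal) > 0) {
    abort(sprintf("illegal character in dot-bracket string: '%s'", illegal[1]))
  }
  stack <- integer(0)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (length(stack) == 0) abort("unbalanced parentheses: unmatched ')'")
      pairs_i <- c(pairs_i, stack[length(stack)])
      pairs_j <- c(pairs_j, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) abort("unbalanced parentheses: unmatched '('")
  ord <- order(pairs_i)
  structure(list(structure = text, length = length(chars),
                 pairs = tibble(i = pairs_i[ord], j = pairs_j[ord])),
            class = "dot_bracket")
}

#' @export
print.dot_bracket <- function(x, ...) {
  cat(sprintf("<dot_bracket> length %d, %d pairs\n", x$length, nrow(x$pairs)))
  invisible(x)
}

#' Read / write a pairwise genome offset map
#'
#' Blockwise coordinate correspondence between two genomes, the consumable
#' form of a whole-genome alignment.  Columns: `a_start`, `a_end`, `b_start`,
#' `b_end`, `orientation` (`"+"` collinear, `"-"` reverse).  Blocks must not
#' overlap within either genome.
#'
#' @param path TSV file path.
#' @return A tibble of blocks (class `offset_map`).
#' @export
read_offset_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    a_start = readr::col_integer(), a_end = readr::col_integer(),
    b_start = readr::col_integer(), b_end = readr::col_integer(),
    orientation = readr::col_character()
  ), progress = FALSE)
  offset_map(tbl)
}

#' @rdname read_offset_map
#' @param blocks Data frame of alignment blocks.
#' @export
offset_map <- function(blocks) {
  blocks <- as_tibble(blocks)[, c("a_start", "a_end", "b_start", "b_end",
                                  "orientation")]
  stopifnot(all(blocks$a_start <= blocks$a_end),
            all(blocks$b_start <= blocks$b_end),
            all(blocks$orientation %in% c("+", "-")),
            all(blocks$a_end - blocks$a_start == blocks$b_end - blocks$b_start))
  for (side in c("a", "b")) {
    s <- blocks[[paste0(side, "_start")]]
    e <- blocks[[paste0(side, "_end")]]
    ord <- order(s)
    if (any(s[ord][-1] <= e[ord][-length(e)])) {
      abort(sprintf("offset-map blocks overlap within genome %s", toupper(side)))
    }
  }
  class(blocks) <- c("offset_map", class(blocks))
  blocks
}

#' @rdname read_offset_map
#' @param map Offset map to write.
#' @export
write_offset_map <- function(map, path) {
  readr::write_tsv(as_tibble(unclass(map)), path, progress = FALSE)
  invisible(map)
}

#' Read / write a per-base coverage vector
#'
#' Sparse TSV of `pos`, `depth`; positions absent from the file have depth 0.
#'
#' @param path TSV file path.
#' @return Tibble with integer `pos` and `depth`.
#' @export
read_coverage <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(), depth = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname read_coverage
#' @param coverage Tibble with columns `pos`, `depth`.
#' @export
write_coverage <- function(coverage, path) {
  readr::write_tsv(coverage[, c("pos", "depth")], path, progress = FALSE)
  invisible(coverage)
}

#' Extract a feature sequence from a genome, strand-aware
#'
#' @param genome A [genome_record()].
#' @param start,end 1-based inclusive genomic interval.
#' @param strand `"+"` or `"-"`; minus-strand sequences are
#'   reverse-complemented so the result reads 5'→3' on the feature strand.
#' @return Nucleotide string.
#' @export
feature_seq <- function(genome, start, end, strand = "+") {
  assert_scalar_interval(start, end)
  if (end > nchar(genome$sequence)) abort("interval beyond genome end")
  s <- substr(genome$sequence, start, end)
  if (strand == "-") s <- revcomp(s)
  s
}
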