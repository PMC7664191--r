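# Readers and writers for the standard formats the pipeline touches:
# BED intervals, FASTA, JASPAR-PFM / MEME-minimal motif libraries,
# expression / DE tables (TSV), TF lists, GMT gene sets, ortholog maps.
# Coordinates are 0-based half-open throughout.

#' Read genomic intervals from a BED file
#'
#' BED3/4/6 are accepted; 0-based half-open coordinates. When the name
#' column is absent, names `region_<i>` are generated. Lines starting with
#' `track`, `browser` or `#` are ignored.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  n <- length(lines)
  if (n == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("read_bed: line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns")
  getcol <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(getcol(2)))
  end <- suppressWarnings(as.integer(getcol(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("read_bed: line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start < 0)
  if (length(bad))
    stop("read_bed: line ", lineno[bad[1]], ": negative start")
  bad <- which(end <= start)
  if (length(bad))
    stop("read_bed: line ", lineno[bad[1]], ": end <= start")
  name <- ifelse(nf >= 4, getcol(4), sprintf("region_%d", seq_len(n)))
  strand <- ifelse(nf >= 6, getcol(6), ".")
  if (!all(strand %in% c("+", "-", ".")))
    stop("read_bed: invalid strand value(s)")
  dup <- name[duplicated(name)]
  if (length(dup))
    stop("read_bed: duplicate interval name(s): ",
         paste(unique(dup), collapse = ", "))
  data.frame(chrom = getcol(1), start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED
#' @param intervals data.frame with chrom, start, end, name (strand optional).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end", "name")]
  if (!is.null(intervals$strand)) {
    df$score <- 0L
    df$strand <- intervals$strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased; record ids are truncated at the first
#' whitespace; IUPAC ambiguity codes other than N are converted to N (with
#' a message reporting how many).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences over A,C,G,T,N.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("read_fasta: no sequences in ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs)))
    stop("read_fasta: duplicate sequence ids in ", path)
  n_amb <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), integer(1)))
  if (n_amb > 0) {
    message("read_fasta: converted ", n_amb, " ambiguity base(s) to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  if (any(!nzchar(seqs))) stop("read_fasta: empty sequence record")
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract enhancer sequences from a genome
#'
#' Intervals are 0-based half-open, applied directly to the genome strings.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param intervals data.frame from [read_bed()].
#' @return Named character vector (names = interval names).
#' @export
extract_sequences <- function(genome, intervals) {
  missing_chr <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chr))
    stop("extract_sequences: chromosome(s) not in genome: ",
         paste(missing_chr, collapse = ", "))
  too_far <- intervals$end > nchar(genome[intervals$chrom])
  if (any(too_far))
    stop("extract_sequences: interval(s) beyond chromosome end: ",
         paste(intervals$name[too_far], collapse = ", "))
  stats::setNames(substring(genome[intervals$chrom], intervals$start + 1L,
                            intervals$end),
                  intervals$name)
}

#' Read a motif library
#'
#' Supports JASPAR PFM (count matrices; converted to probabilities with a
#' per-cell pseudocount) and the minimal MEME text dialect (probability
#' matrices, used as stored). An empty file yields an empty library with a
#' warning.
#'
#' @param path Path to the motif file.
#' @param format `"jaspar-pfm"` or `"meme-minimal"`.
#' @param pseudocount Per-cell pseudocount for count matrices.
#' @param background Default background used when the file states none.
#' @return List of `pwm` objects, named by motif_id.
#' @export
read_motif_library <- function(path, format = c("jaspar-pfm", "meme-minimal"),
                               pseudocount = 0.25,
                               background = rep(0.25, 4)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_motif_library: file not found: ", path)
  lines <- readLines(path)
  pwms <- if (format == "jaspar-pfm") {
    .parse_jaspar(lines, pseudocount, background)
  } else {
    .parse_meme(lines, background)
  }
  if (length(pwms) == 0)
    warning("read_motif_library: no motifs found in ", path)
  names(pwms) <- vapply(pwms, function(p) p$motif_id, character(1))
  pwms
}

.parse_numbers <- function(line) {
  nums <- regmatches(line, gregexpr("[-0-9.eE+]+", line))[[1]]
  suppressWarnings(as.numeric(nums))
}

.parse_jaspar <- function(lines, pseudocount, background) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  pwms <- list()
  for (i in seq_along(hdr)) {
    h <- hdr[i]
    last <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    toks <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    id <- toks[1]
    altname <- if (length(toks) > 1) toks[2] else NULL
    body <- lines[(h + 1):last]
    if (h + 1 > last || length(body) != 4)
      stop("read_motif_library: motif '", id, "': expected 4 matrix rows, got ",
           max(0, last - h))
    # rows may be labelled ("A [ 1 2 3 ]") or bare numbers
    rows <- lapply(body, function(b) .parse_numbers(sub("^\\s*[ACGTacgt]", "", b)))
    if (length(unique(lengths(rows))) != 1)
      stop("read_motif_library: motif '", id, "': ragged count rows")
    counts <- do.call(rbind, rows)
    if (anyNA(counts))
      stop("read_motif_library: motif '", id, "': non-numeric counts")
    pwms[[length(pwms) + 1]] <-
      pwm_from_counts(id, counts, pseudocount = pseudocount,
                      background = background, altname = altname)
  }
  pwms
}

.parse_meme <- function(lines, background) {
  pwms <- list()
  bg <- background
  i <- 1
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^Background letter frequencies", line) && i < n) {
      v <- .parse_numbers(lines[i + 1])
      if (length(v) == 4) bg <- v / sum(v)
      i <- i + 2
    } else if (grepl("^MOTIF\\b", line)) {
      toks <- strsplit(line, "\\s+")[[1]]
      id <- toks[2]
      altname <- if (length(toks) > 2) toks[3] else NULL
      # find the letter-probability header
      j <- i + 1
      while (j <= n && !grepl("^letter-probability matrix", trimws(lines[j])))
        j <- j + 1
      if (j > n)
        stop("read_motif_library: motif '", id,
             "': no letter-probability matrix")
      w <- suppressWarnings(as.integer(
        sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
      rows <- list()
      j <- j + 1
      while (j <= n) {
        v <- .parse_numbers(lines[j])
        if (length(v) == 0) break
        if (length(v) != 4)
          stop("read_motif_library: motif '", id,
               "': probability row without 4 values")
        rows[[length(rows) + 1]] <- v
        j <- j + 1
        if (!is.na(w) && length(rows) == w) break
      }
      if (!is.na(w) && length(rows) != w)
        stop("read_motif_library: motif '", id, "': expected ", w,
             " rows, got ", length(rows))
      probs <- t(do.call(rbind, rows))
      cs <- colSums(probs)
      if (any(cs == 0))
        stop("read_motif_library: motif '", id, "': zero-total column")
      if (any(abs(cs - 1) > 0.01))
        stop("read_motif_library: motif '", id,
             "': probability column(s) far from 1")
      probs <- sweep(probs, 2, cs, "/")
      pwms[[length(pwms) + 1]] <-
        new_pwm(id, probs, background = bg, altname = altname)
      i <- j
    } else {
      i <- i + 1
    }
  }
  pwms
}

#' Write a motif library in minimal MEME format
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_motif_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- if (length(pwms)) pwms[[1]]$background else rep(0.25, 4)
  writeLines(sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
             con)
  for (p in pwms) {
    writeLines(c("", paste("MOTIF", p$motif_id,
                           if (!is.null(p$altname)) p$altname else "")), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       pwm_width(p)), con)
    writeLines(apply(p$probs, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a two-condition expression table
#'
#' TSV with header columns gene_id, fpkm_a, fpkm_b, fold, q_value (extra
#' columns are kept). When `fold` is absent it is computed as
#' fpkm_b / fpkm_a (+Inf when fpkm_a is 0 and fpkm_b > 0; NA when both are
#' 0); a deposited fold column, when present, is used as-is since upstream
#' normalisation may differ from the plain FPKM ratio.
#'
#' @param path Path to the TSV.
#' @return data.frame of expression records.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "fpkm_a", "fpkm_b", "q_value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("read_expression_table: missing column(s) ",
         paste(missing, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "))
  for (col in c("fpkm_a", "fpkm_b", "q_value", intersect("fold", names(df)))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$fpkm_a < 0, na.rm = TRUE) || any(df$fpkm_b < 0, na.rm = TRUE))
    stop("read_expression_table: negative FPKM value(s)")
  if (any(df$q_value < 0 | df$q_value > 1, na.rm = TRUE))
    stop("read_expression_table: q_value outside [0, 1]")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("read_expression_table: duplicate gene_id(s): ",
         paste(dup, collapse = ", "))
  if (!"fold" %in% names(df)) {
    df$fold <- ifelse(df$fpkm_a > 0, df$fpkm_b / df$fpkm_a,
                      ifelse(df$fpkm_b > 0, Inf, NA_real_))
  }
  df
}

#' Read a knockdown differential-expression table
#'
#' TSV with header columns gene, log2fc, padj.
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("gene", "log2fc", "padj"), names(df))
  if (length(missing))
    stop("read_de_table: missing column(s) ", paste(missing, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  df$log2fc <- as.numeric(df$log2fc)
  df$padj <- as.numeric(df$padj)
  df
}

#' Read a TF catalog (one gene symbol per line)
#' @param path Path to the list file.
#' @return Character vector of upper-cased symbols.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  unique(toupper(x[nzchar(x)]))
}

#' Read gene sets in GMT format
#'
#' Each line is term, description, then member genes. Gene symbols are
#' upper-cased (symbol matching is case-insensitive throughout) and
#' deduplicated within a term.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("read_gmt: line ", short[1], ": fewer than 3 fields")
  terms <- vapply(fields, `[`, character(1), 1)
  dup <- unique(terms[duplicated(terms)])
  if (length(dup))
    stop("read_gmt: duplicate term(s): ", paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  stats::setNames(sets, terms)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(term, desc, genes)
    paste(c(term, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an enhancer-to-ortholog map
#'
#' TSV with header columns `enhancer` and `ortholog`. Enhancers absent from
#' the map are treated as having no ortholog (non-conserved) downstream.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns enhancer, ortholog.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("enhancer", "ortholog"), names(df))
  if (length(missing))
    stop("read_ortholog_map: missing column(s) ",
         paste(missing, collapse = ", "))
  dup <- unique(df$enhancer[duplicated(df$enhancer)])
  if (length(dup))
    stop("read_ortholog_map: duplicate enhancer(s): ",
         paste(dup, collapse = ", "))
  df[, c("enhancer", "ortholog")]
}

#' Write a result table as TSV
#'
#' Floating-point columns are serialised at 6 significant digits; row order
#' is taken as given (modules rank their results before writing), so equal
#' inputs produce byte-identical files.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  df <- table
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- vapply(signif(df[[col]], 6), function(v)
        if (is.na(v)) "NA" else as.character(v), character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
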