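#' @title Reference sequences, variant lists and mutation-pair extraction
#' @description Load a reference genome from FASTA, read labeled SNVs from
#'   VCF or TSV, and extract the 2 x L stacked nucleotide-context matrix
#'   (reference row / mutated row) around each variant.
#' @name variant_windows
NULL

SEQ_ALPHABET <- c("a", "c", "g", "n", "t")

#' Load a reference genome from a FASTA file
#'
#' Sequences are lowercased and every symbol outside \{a,c,g,t\} (ambiguity
#' codes, gaps) is mapped to `n`, the missing-place indicator used
#' throughout the sequence pipeline.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return an object of class `ref_store`: a named character vector of
#'   lowercase sequences, one element per chromosome.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA record identifier(s): ", paste(dup, collapse = ", "))
  }
  chars <- tolower(as.character(seqs))
  chars <- gsub("[^acgt]", "n", chars)
  names(chars) <- ids
  structure(chars, class = "ref_store")
}

#' @export
print.ref_store <- function(x, ...) {
  cat("Reference store:", length(x), "sequence(s)\n")
  for (nm in names(x)) cat(sprintf("  %s  (%d bp)\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Chromosome lengths of a reference store
#' @param store a `ref_store`.
#' @return named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(store) {
  stopifnot(inherits(store, "ref_store"))
  vapply(unclass(store), nchar, integer(1))
}

normalize_label <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  lx[is.na(lx) | lx == "" | lx == "."] <- "unlabeled"
  bad <- !lx %in% c("driver", "passenger", "unlabeled")
  if (any(bad)) {
    stop("unrecognized label value(s): ", paste(unique(lx[bad]), collapse = ", "))
  }
  lx
}

new_variants <- function(chrom, pos, ref, alt, label) {
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    label = normalize_label(label),
    stringsAsFactors = FALSE
  )
  bad_pos <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad_pos) > 0L) stop("non-positive or missing POS at row ", bad_pos[1])
  df
}

#' Read a variant list from TSV or VCF
#'
#' Only biallelic single-nucleotide substitutions are kept: rows whose REF
#' or ALT is not a single base in \{A,C,G,T\}, or with multiple ALT alleles,
#' are skipped and counted (see the `skipped` attribute). Rows with
#' REF == ALT are rejected and counted separately (`rejected` attribute).
#' Labels are normalized to `driver` / `passenger` / `unlabeled`.
#'
#' @param path input file.
#' @param format `"tsv"` (columns CHR, POS, REF, ALT, optional LABEL; header
#'   optional) or `"vcf"` (v4.x; the LABEL may be carried in the ID column).
#' @return a data.frame with columns `chrom`, `pos`, `ref`, `alt`, `label`
#'   and attributes `skipped` (non-SNV rows) and `rejected` (REF == ALT).
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("variant file not found: ", path)
  if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    toupper(ref) %in% c("A", "C", "G", "T") &
    toupper(alt) %in% c("A", "C", "G", "T")
}

read_variants_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no variant rows in ", path)
  fields <- strsplit(lines, "[\t ]+")
  # tolerate a header row naming the columns
  start <- 1L
  if (grepl("^(chr|chrom)$", tolower(fields[[1]][1])) ||
      isTRUE(tolower(fields[[1]][2]) == "pos")) {
    start <- 2L
  }
  if (start > length(fields)) stop("no variant rows in ", path)
  rows <- vector("list", length(fields))
  skipped <- 0L; rejected <- 0L
  for (i in seq(start, length(fields))) {
    f <- fields[[i]]
    if (length(f) < 4L) stop("malformed TSV row at line ", i, ": ", lines[i])
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("non-integer POS at line ", i, ": ", lines[i])
    if (!is_snv(f[3], f[4])) { skipped <- skipped + 1L; next }
    if (toupper(f[3]) == toupper(f[4])) { rejected <- rejected + 1L; next }
    rows[[i]] <- list(chrom = f[1], pos = pos, ref = f[3], alt = f[4],
                      label = if (length(f) >= 5L) f[5] else NA_character_)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no usable SNV rows in ", path)
  df <- new_variants(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(r) r$pos, integer(1)),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    label = vapply(rows, `[[`, "", "label")
  )
  attr(df, "skipped") <- skipped
  attr(df, "rejected") <- rejected
  df
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  multi <- grepl(",", alt)
  keep <- !multi & is_snv(ref, alt)
  skipped <- sum(!keep)
  same <- keep & toupper(ref) == toupper(alt)
  rejected <- sum(same)
  keep <- keep & !same
  if (!any(keep)) stop("no usable SNV rows in ", path)
  id <- fx[, "ID"]
  label <- ifelse(tolower(id) %in% c("driver", "passenger"), tolower(id), NA_character_)
  df <- new_variants(
    chrom = fx[keep, "CHROM"], pos = as.integer(fx[keep, "POS"]),
    ref = ref[keep], alt = alt[keep], label = label[keep]
  )
  attr(df, "skipped") <- skipped
  attr(df, "rejected") <- rejected
  df
}

#' Extract the 2 x L reference/mutant context pair around one variant
#'
#' Row 0 is the reference context of length L = 2w + 1 centered on the
#' variant position; row 1 is identical except that the center symbol is
#' replaced by the alternate base, so the two rows differ in exactly one
#' column. Positions falling outside the chromosome are padded with `n`.
#'
#' @param store a `ref_store` from [load_reference()].
#' @param variant a one-row variant data.frame (or a list with `chrom`,
#'   `pos`, `ref`, `alt`, optionally `label`).
#' @param w window radius (>= 1); the context length is `2 * w + 1`.
#' @param on_ref_mismatch what to do when the stored base at `pos` differs
#'   from the variant's REF: `"reject"` (error) or `"warn"` (warn and use
#'   the store's base as the reference row center).
#' @return an object of class `mutation_pair`: a list with `w`, `ref_row`
#'   and `alt_row` (lowercase strings of length L) and the source `variant`.
#' @export
extract_pair <- function(store, variant, w,
                         on_ref_mismatch = c("reject", "warn")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  stopifnot(inherits(store, "ref_store"))
  if (w < 1L) stop("window radius w must be >= 1")
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- tolower(as.character(variant$ref))
  alt <- tolower(as.character(variant$alt))
  if (!chrom %in% names(store)) stop("chromosome not in reference store: ", chrom)
  if (ref == alt) stop("REF == ALT for variant at ", chrom, ":", pos)
  seq <- unclass(store)[[chrom]]
  len <- nchar(seq)
  if (pos < 1L || pos > len) stop("position out of range: ", chrom, ":", pos)
  lo <- pos - w; hi <- pos + w
  core <- substr(seq, max(1L, lo), min(len, hi))
  left_pad <- strrep("n", max(0L, 1L - lo))
  right_pad <- strrep("n", max(0L, hi - len))
  ref_row <- paste0(left_pad, core, right_pad)
  center <- substr(ref_row, w + 1L, w + 1L)
  if (center != ref) {
    msg <- sprintf("reference mismatch at %s:%d: store has '%s', variant REF is '%s'",
                   chrom, pos, center, ref)
    if (on_ref_mismatch == "reject") stop(msg)
    warning(msg, "; using the store's base")
  }
  alt_row <- ref_row
  substr(alt_row, w + 1L, w + 1L) <- alt
  structure(
    list(w = as.integer(w), ref_row = ref_row, alt_row = alt_row,
         variant = list(chrom = chrom, pos = pos,
                        ref = toupper(substr(ref_row, w + 1L, w + 1L)),
                        alt = toupper(alt),
                        label = if (!is.null(variant$label)) as.character(variant$label)
                                else "unlabeled")),
    class = "mutation_pair"
  )
}

#' @export
print.mutation_pair <- function(x, ...) {
  v <- x$variant
  cat(sprintf("MutationPair %s:%d %s>%s (%s), w = %d, L = %d\n",
              v$chrom, v$pos, v$ref, v$alt, v$label, x$w, 2L * x$w + 1L))
  trim <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat("  ref:", trim(x$ref_row), "\n  alt:", trim(x$alt_row), "\n")
  invisible(x)
}

#' Extract context pairs for a whole variant table
#'
#' @inheritParams extract_pair
#' @param variants a variant data.frame from [read_variants()] or
#'   [generate_variants()].
#' @return a list of `mutation_pair` objects, one per variant row.
#' @export
extract_pairs <- function(store, variants, w,
                          on_ref_mismatch = c("reject", "warn")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  lapply(seq_len(nrow(variants)), function(i) {
    extract_pair(store, variants[i, , drop = FALSE], w, on_ref_mismatch)
  })
}

#' Write extracted pairs to a tab-separated file
#'
#' Columns: chrom, pos, ref, alt, label, ref_row, alt_row.
#' @param pairs list of `mutation_pair` objects.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(chrom = p$variant$chrom, pos = p$variant$pos,
               ref = p$variant$ref, alt = p$variant$alt,
               label = p$variant$label,
               ref_row = p$ref_row, alt_row = p$alt_row,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
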