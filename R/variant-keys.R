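#' Normalize variant representations into matching keys
#'
#' Different call sets frequently represent the same indel differently
#' (anchored VCF style, shifted within a repeat context, padded alleles).
#' `normalize_variant_key()` reduces each `(chrom, pos, ref, alt)` record to a
#' canonical key so that calls can be matched across pipelines, panels of
#' normals, and validation call lists. The reduction is parsimony trimming:
#' the shared allele suffix is removed first, then the shared prefix (the
#' position advancing accordingly), leaving a minimal -- possibly empty --
#' allele pair. When a reference sequence is supplied, indels are additionally
#' left-aligned by shifting through repeat context, the VCF convention.
#'
#' @param chrom Character vector of contig names. A leading `"chr"` prefix is
#'   stripped so that `"chr1"` and `"1"` records match.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of upper-case `A`/`C`/`G`/`T`/`N` alleles.
#' @param reference Optional named list or character vector mapping contig
#'   name to its sequence (position 1 of the string = position 1 of the
#'   contig). When supplied, trimmed indels are left-aligned against it.
#' @return A character vector of keys, `"chrom:pos:REF>ALT"`, with an empty
#'   allele rendered as `"-"`.
#' @examples
#' normalize_variant_key("chr1", 100, "A", "T")
#' # two representations of one deletion in an AT context collapse:
#' normalize_variant_key("1", c(100, 101), c("CA", "AT"), c("C", "T"))
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt, reference = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  assert_that(all(pos >= 1L), "positions must be >= 1")
  bad <- !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt)
  if (any(bad)) {
    stop("alleles must be non-empty A/C/G/T/N strings; offending rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  assert_that(all(ref != alt), "ref and alt must differ")

  chrom <- sub("^chr", "", chrom)

  # fast path: SNVs need no normalization
  needs <- nchar(ref) > 1L | nchar(alt) > 1L
  for (i in which(needs)) {
    trimmed <- trim_alleles(pos[i], ref[i], alt[i])
    if (!is.null(reference) && (trimmed$ref == "" || trimmed$alt == "")) {
      ctg <- reference[[chrom[i]]]
      if (!is.null(ctg)) trimmed <- left_align(trimmed, ctg)
    }
    pos[i] <- trimmed$pos; ref[i] <- trimmed$ref; alt[i] <- trimmed$alt
  }
  paste0(chrom, ":", pos, ":",
         ifelse(ref == "", "-", ref), ">", ifelse(alt == "", "-", alt))
}

# full shared-suffix then shared-prefix trim; empty alleles allowed
trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 0 && length(a) > 0 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# shift a trimmed insertion/deletion left through repeat context
left_align <- function(v, contig) {
  seq <- if (v$ref == "") v$alt else v$ref
  pos <- v$pos
  repeat {
    if (pos <= 1L) break
    prev <- substr(contig, pos - 1L, pos - 1L)
    if (prev == "" || prev != substr(seq, nchar(seq), nchar(seq))) break
    seq <- paste0(prev, substr(seq, 1L, nchar(seq) - 1L))
    pos <- pos - 1L
  }
  if (v$ref == "") list(pos = pos, ref = "", alt = seq)
  else list(pos = pos, ref = seq, alt = "")
}

#' Add a normalized `key` column to a variant table
#'
#' @param variants A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @param reference Optional reference passed to [normalize_variant_key()].
#' @return The input as a tibble with a `key` character column appended (an
#'   existing `key` column is left untouched).
#' @export
add_variant_key <- function(variants, reference = NULL) {
  variants <- as_tibble(variants)
  if (!is.null(variants[["key"]])) return(variants)
  variants$key <- normalize_variant_key(
    variants$chrom, variants$pos, variants$ref, variants$alt, reference
  )
  variants
}
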