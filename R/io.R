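#' Read a variant table from MAF-like TSV or VCF
#'
#' Both formats are normalized to the internal convention: 1-based
#' positions, contig names without a `chr` prefix, one row per variant per
#' sample, with `vaf` derived from alt and total read counts where
#' available. Inputs mixing `chr1`- and `1`-style contig names are
#' rejected, as are symbolic ALT alleles (`<DEL>` etc.) and malformed rows
#' (reported with their row numbers).
#'
#' @param path File path.
#' @param format `"maf"` for MAF-like TSV (columns `Hugo_Symbol`,
#'   `Chromosome`, `Start_Position`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2`, `Variant_Classification`, `t_alt_count`,
#'   `t_depth`, `Tumor_Sample_Barcode`) or `"vcf"` for VCF 4.x.
#' @return Tibble of variant calls.
#' @export
read_variants <- function(path, format = c("maf", "vcf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("file not found:", path))
  if (format == "maf") read_variants_maf(path) else read_variants_vcf(path)
}

check_contig_style <- function(chrom) {
  has_chr <- grepl("^chr", chrom)
  if (any(has_chr) && !all(has_chr)) {
    stop("mixed contig naming styles ('chr1' and '1') in one input",
         call. = FALSE)
  }
  sub("^chr", "", chrom)
}

read_variants_maf <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  needed <- c("Hugo_Symbol", "Chromosome", "Start_Position",
              "Reference_Allele", "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0,
              paste("MAF input lacks columns:", paste(missing, collapse = ", ")))
  bad <- which(is.na(df$Start_Position) | is.na(df$Reference_Allele) |
                 is.na(df$Tumor_Seq_Allele2))
  if (length(bad) > 0) {
    stop("malformed MAF rows: ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    chrom = check_contig_style(as.character(df$Chromosome)),
    pos = as.integer(df$Start_Position),
    ref = df$Reference_Allele,
    alt = df$Tumor_Seq_Allele2,
    gene = df$Hugo_Symbol
  )
  if (!is.null(df[["Variant_Classification"]])) {
    out$consequence <- df$Variant_Classification
  }
  if (!is.null(df[["t_alt_count"]]) && !is.null(df[["t_depth"]])) {
    out$alt_count <- as.integer(df$t_alt_count)
    out$depth <- as.integer(df$t_depth)
    out$vaf <- out$alt_count / out$depth
  }
  out
}

read_variants_vcf <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "##")]
  assert_that(length(body) >= 1 && startsWith(body[1], "#CHROM"),
              "not a VCF: missing #CHROM header")
  header <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character()))
  }
  fields <- strsplit(rows, "\t")
  lens <- lengths(fields)
  if (any(lens < 8)) {
    stop("malformed VCF rows: ", paste(utils::head(which(lens < 8), 10),
                                       collapse = ", "), call. = FALSE)
  }
  mat <- t(vapply(fields, function(f) f[1:8], character(8)))
  alt <- mat[, 5]
  symbolic <- grepl("[<>]|\\[|\\]", alt)
  if (any(symbolic)) {
    stop("symbolic ALT alleles are not supported (rows ",
         paste(utils::head(which(symbolic), 10), collapse = ", "), ")",
         call. = FALSE)
  }
  sample_col <- if (length(header) >= 10) header[10] else NA_character_
  tibble(
    sample_id = rep(sample_col, nrow(mat)),
    chrom = check_contig_style(mat[, 1]),
    pos = as.integer(mat[, 2]),
    ref = mat[, 4],
    alt = alt
  ) %>% tidyr::separate_longer_delim("alt", ",")
}

#' Write a variant table as MAF-like TSV
#'
#' @param variants Internal variant tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variants_maf <- function(variants, path) {
  n <- nrow(variants)
  blank <- function(col, default) variants[[col]] %||% rep(default, n)
  out <- tibble(
    Hugo_Symbol = blank("gene", NA_character_),
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Classification = blank("consequence", NA_character_),
    t_alt_count = blank("alt_count", NA_integer_),
    t_depth = blank("depth", NA_integer_),
    Tumor_Sample_Barcode = variants$sample_id
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a minimal VCF 4.2 file
#'
#' @param variants Variant tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", ".", sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write clinical tables
#'
#' Plain TSV with one row per patient; logical columns round-trip as
#' TRUE/FALSE.
#'
#' @param path File path.
#' @return `read_clinical()` returns a tibble.
#' @export
read_clinical <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}

#' Read BED regions (0-based half-open)
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                  col_types = "cii", comment = "#") %>%
    mutate(chrom = check_contig_style(.data$chrom))
}
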