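#' Write a gaze recording to the TSV dialect
#'
#' Samples: columns time_ms, x_deg, y_deg, blink (0/1); messages: columns
#' time_ms, event. Coordinates are degrees of visual angle, screen-centre
#' origin, rightward/upward positive.
#'
#' @param recording a gaze recording (samples, messages, sampling_rate).
#' @param gaze_path,messages_path output files.
#' @export
write_gaze_tsv <- function(recording, gaze_path, messages_path) {
  utils::write.table(recording$samples, gaze_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(recording$messages, messages_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(gaze_path)
}

#' Read a gaze recording from the TSV dialect
#'
#' @param gaze_path,messages_path files written by [write_gaze_tsv()].
#' @param sampling_rate Hz; inferred from the median sampling interval when
#'   omitted.
#' @return a gaze recording list.
#' @export
read_gaze_tsv <- function(gaze_path, messages_path,
                          sampling_rate = NULL) {
  s <- utils::read.delim(gaze_path, stringsAsFactors = FALSE)
  m <- utils::read.delim(messages_path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_ms", "x_deg", "y_deg", "blink") %in% names(s)),
            all(diff(s$time_ms) > 0))
  if (is.null(sampling_rate))
    sampling_rate <- 1000 / stats::median(diff(s$time_ms))
  list(samples = s, messages = m, sampling_rate = sampling_rate)
}

#' Minimal EyeLink ASC-style importer
#'
#' Parses the plain-text ASC dialect: sample lines start with a numeric
#' timestamp followed by x, y (and pupil) fields, with "." marking missing
#' data (treated as blink samples); MSG lines carry "MSG <time> <text>".
#' Coordinates are passed through unchanged and are expected in degrees.
#'
#' @param path ASC file.
#' @param sampling_rate Hz; inferred when omitted.
#' @return a gaze recording list.
#' @export
read_asc <- function(path, sampling_rate = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tok1 <- sub("[\t ].*$", "", lines)
  is_msg <- tok1 == "MSG"
  is_sample <- grepl("^[0-9]", tok1)
  parse_fields <- function(l) strsplit(l, "[\t ]+")
  sm <- parse_fields(lines[is_sample])
  num <- function(v) suppressWarnings(as.numeric(v))
  time <- vapply(sm, function(p) num(p[1]), numeric(1))
  x <- vapply(sm, function(p) num(p[2]), numeric(1))
  y <- vapply(sm, function(p) num(p[3]), numeric(1))
  blink <- as.integer(is.na(x) | is.na(y))
  msgs <- parse_fields(lines[is_msg])
  messages <- data.frame(
    time_ms = vapply(msgs, function(p) num(p[2]), numeric(1)),
    event = vapply(msgs, function(p) paste(p[-(1:2)], collapse = " "),
                   character(1)), stringsAsFactors = FALSE)
  o <- order(time)
  samples <- data.frame(time_ms = time[o], x_deg = x[o], y_deg = y[o],
                        blink = blink[o])
  if (is.null(sampling_rate))
    sampling_rate <- 1000 / stats::median(diff(samples$time_ms))
  list(samples = samples, messages = messages,
       sampling_rate = sampling_rate)
}

#' Write/read a dosage matrix as TSV
#'
#' Rows are subjects (first column subject_id), columns are variant ids.
#' @param genotypes dosage matrix with dimnames.
#' @param path file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "double"
  m
}

#' Write/read a PLINK-score-style weight table
#'
#' Four tab-separated columns: variant_id, effect_allele, weight, pvalue;
#' the first three are PLINK score-file compatible.
#' @param weights weight table data frame.
#' @param path file.
#' @export
write_weight_tsv <- function(weights, path) {
  utils::write.table(weights[, c("variant_id", "effect_allele", "weight",
                                 "pvalue")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weight_tsv
#' @export
read_weight_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write genotype dosages as a VCF with a DS FORMAT field
#'
#' REF is the other allele and ALT the effect allele, so DS counts the
#' effect allele. Missing dosages are written as ".".
#'
#' @param genotypes dosage matrix (subjects x variants).
#' @param variants variant table (id, chrom, pos, effect_allele,
#'   other_allele).
#' @param path output .vcf file (plain text).
#' @export
write_vcf_dosage <- function(genotypes, variants, path) {
  v <- variants[match(colnames(genotypes), variants$id), ]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                  "Description=\"Estimated alternate allele dosage\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    ds <- genotypes[, j]
    ds <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS", ds),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS field
#'
#' @param path a VCF file.
#' @return list with \code{dosages} (subjects x variants) and
#'   \code{variants} (id, chrom, pos, effect_allele = ALT, other_allele =
#'   REF).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS")
  m <- t(apply(ds, 2, as.numeric))
  ## apply() drops to a vector for a single sample
  if (is.null(dim(m))) m <- matrix(m, ncol = nrow(ds))
  dimnames(m) <- list(colnames(ds), rownames(ds))
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(id = fx$ID, chrom = fx$CHROM,
                         pos = as.integer(fx$POS),
                         effect_allele = fx$ALT, other_allele = fx$REF,
                         stringsAsFactors = FALSE)
  list(dosages = m, variants = variants)
}

#' Write/read a cohort table as TSV
#' @param data data frame, one row per subject.
#' @param path file.
#' @export
write_cohort_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
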