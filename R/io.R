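#' File readers and writers for the standard plain-text formats
#'
#' All coordinates on disk follow the native convention of the format:
#' BED/refFlat/bedgraph are 0-based half-open, VCF is 1-based. Readers
#' convert to the package's internal BED convention.
#'
#' @name io
NULL

#' Read a BED3/BED6 file
#' @param path file path.
#' @return data.table with chrom/start/end (+ name/score/strand if BED6).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, cols[seq_len(ncol(dt))])
  dt[]
}

#' Write intervals as BED
#' @param dt interval data.frame (chrom/start/end, optional name, score,
#'   strand).
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  data.table::fwrite(data.table::as.data.table(dt)[, keep, with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a refFlat transcript table
#'
#' Standard 11-column UCSC refFlat: geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds,
#' with comma-terminated exon lists. Coordinates are already 0-based
#' half-open.
#'
#' @param path file path.
#' @return a `transcript_models` data.table.
#' @export
read_refflat <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(10, 11)))
  data.table::setnames(dt, c("gene_name", "tx_id", "chrom", "strand",
                             "tx_start", "tx_end", "cds_start", "cds_end",
                             "exon_count", "exon_starts", "exon_ends"))
  validate_transcripts(dt)
  data.table::setattr(dt, "class",
                      c("transcript_models", class(dt)))
  dt[]
}

#' Write a refFlat transcript table
#' @param models transcript table as produced by [read_refflat()] or
#'   [simulate_genome()].
#' @param path output path.
#' @export
write_refflat <- function(models, path) {
  dt <- data.table::as.data.table(models)
  if (!"exon_count" %in% names(dt))
    dt[, exon_count := vapply(exon_starts, function(x)
      length(exon_list(x)), integer(1))]
  norm <- function(x) vapply(x, function(v)
    paste0(paste(exon_list(v), collapse = ","), ","), character(1))
  out <- dt[, .(gene_name, tx_id, chrom, strand, tx_start, tx_end,
                cds_start, cds_end, exon_count,
                exon_starts = norm(exon_starts),
                exon_ends = norm(exon_ends))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV (faidx-style)
#' @param path file path.
#' @return named integer vector chrom -> length.
#' @export
read_genome_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  stats::setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}

#' @rdname read_genome_sizes
#' @param genome_sizes named vector chrom -> length.
#' @export
write_genome_sizes <- function(genome_sizes, path) {
  data.table::fwrite(data.table::data.table(names(genome_sizes),
                                            unname(genome_sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF
#'
#' Parses CHROM/POS/REF/ALT plus total and variant-supporting depths.
#' Depth is taken from `DP=` and `AD=` INFO keys when present (AD as
#' ref,alt), otherwise from a FORMAT/sample column with DP and AD fields.
#' Positions are converted from 1-based VCF to the internal 0-based
#' convention.
#'
#' @param path file path.
#' @param sample_id,genotype,host,replicate metadata attached to the
#'   returned set.
#' @return a `variant_set`.
#' @export
read_vcf_min <- function(path, sample_id = basename(path),
                         genotype = NA_character_, host = NA_character_,
                         replicate = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(variant_set(empty_variants(), sample_id, genotype, host,
                       replicate))
  f <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                         fill = TRUE)
  info <- as.character(f[[8]])
  get_key <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    has <- grepl(paste0("(^|;)", key, "="), info)
    val <- rep(NA_character_, length(info))
    val[has] <- sub(paste0(".*", key, "="), "", m)
    val
  }
  dp <- suppressWarnings(as.integer(get_key("DP")))
  ad <- get_key("AD")
  alt_dp <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1))))
  dt <- data.table::data.table(
    chrom = as.character(f[[1]]), pos = as.integer(f[[2]]) - 1L,
    ref = as.character(f[[4]]), alt = as.character(f[[5]]),
    total_depth = dp, alt_depth = alt_dp)
  variant_set(dt, sample_id, genotype, host, replicate)
}

#' Write a minimal VCF
#' @param vset a `variant_set`.
#' @param path output path.
#' @export
write_vcf_min <- function(vset, path) {
  v <- data.table::as.data.table(vset)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=immunedit"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(v)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d,%d",
    v$chrom, v$pos + 1L, v$ref, v$alt, v$total_depth,
    v$total_depth - v$alt_depth, v$alt_depth) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read RNA-seq reads from FASTA/FASTQ into a read table
#' @param path file path (format inferred from extension; `.gz` allowed).
#' @param sample_id sample label attached to the table.
#' @return data.table with `read_id`, `seq`, `sample_id`.
#' @export
read_reads <- function(path, sample_id = basename(path)) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  data.table::data.table(read_id = names(ss), seq = as.character(ss),
                         sample_id = sample_id)
}

#' Write a read table as FASTA
#' @param reads data.table with `read_id` and `seq`.
#' @param path output path.
#' @export
write_reads_fasta <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- if (inherits(genome, "DNAStringSet")) genome else
    Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a genome FASTA as a named character vector
#' @param path file path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' Read/write a bedgraph coverage profile
#' @param path file path.
#' @return data.table chrom/start/end/depth (0-based half-open runs).
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, c("chrom", "start", "end", "depth"))
  dt[]
}

#' @rdname read_bedgraph
#' @param profile coverage run data.table.
#' @export
write_bedgraph <- function(profile, path) {
  data.table::fwrite(profile[, c("chrom", "start", "end", "depth")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
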