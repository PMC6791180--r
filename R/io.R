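#' Read a Bismark-style per-CpG count table
#'
#' Parses either the 6-column Bismark `.cov` dialect
#' (`chrom, start, end, percent, count_methylated, count_unmethylated`) or the
#' 7-column cytosine report
#' (`chrom, pos, strand, count_methylated, count_unmethylated, context,
#' trinucleotide`). The dialect is auto-detected from the column count.
#' All positions are reported 1-based; the `.cov` dialect carries no strand,
#' which is recorded as `"+"`.
#'
#' Zero-coverage rows (possible in cytosine reports) are retained and flagged
#' in the `zero_cov` column so that their removal by [filter_sites()] is
#' observable; they are not silently dropped at parse time.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `n_meth`, `n_total` and logical `zero_cov`.
#' @seealso [write_coverage_table()] for the inverse operation.
#' @export
#' @examples
#' f <- tempfile(fileext = ".cov")
#' writeLines("chr1\t100\t100\t30\t3\t7", f)
#' read_coverage_table(f)
read_coverage_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      n_meth = integer(), n_total = integer(), zero_cov = logical()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  dialect_cols <- ncols[1]
  if (!dialect_cols %in% c(6L, 7L)) {
    abort_ct("line 1: expected 6 (coverage) or 7 (cytosine report) columns, found %d",
             dialect_cols)
  }
  bad <- which(ncols != dialect_cols)
  if (length(bad) > 0L) {
    abort_ct("line %d: expected %d columns, found %d", bad[1], dialect_cols, ncols[bad[1]])
  }
  mat <- do.call(rbind, fields)
  parse_int <- function(x, what) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) | out != suppressWarnings(as.numeric(x)))
    if (length(bad) > 0L) {
      abort_ct("line %d: malformed %s value '%s'", bad[1], what, x[bad[1]])
    }
    out
  }
  if (dialect_cols == 6L) {
    pos <- parse_int(mat[, 2], "position")
    n_meth <- parse_int(mat[, 5], "methylated count")
    n_unmeth <- parse_int(mat[, 6], "unmethylated count")
    strand <- rep("+", nrow(mat))
  } else {
    pos <- parse_int(mat[, 2], "position")
    strand <- mat[, 3]
    n_meth <- parse_int(mat[, 4], "methylated count")
    n_unmeth <- parse_int(mat[, 5], "unmethylated count")
  }
  if (any(n_meth < 0L) || any(n_unmeth < 0L)) {
    bad <- which(n_meth < 0L | n_unmeth < 0L)[1]
    abort_ct("line %d: negative read count", bad)
  }
  if (any(pos < 1L)) abort_ct("line %d: position must be >= 1", which(pos < 1L)[1])
  tibble(
    chrom = mat[, 1], pos = pos, strand = strand,
    n_meth = n_meth, n_total = n_meth + n_unmeth,
    zero_cov = (n_meth + n_unmeth) == 0L
  )
}

#' Write per-CpG counts in the Bismark coverage dialect
#'
#' The inverse of [read_coverage_table()]: counts round-trip bit-exactly.
#'
#' @param counts A tibble with `chrom`, `pos`, `n_meth`, `n_total`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(counts, path) {
  pct <- ifelse(counts$n_total == 0L, 0, 100 * counts$n_meth / counts$n_total)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   counts$chrom, counts$pos, counts$pos,
                   format(pct, trim = TRUE, scientific = FALSE),
                   counts$n_meth, counts$n_total - counts$n_meth)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read genomic feature intervals from GFF3 or BED
#'
#' All intervals are normalised to the package's internal 1-based inclusive
#' convention: BED (0-based half-open) starts are incremented by 1; GFF3 is
#' already 1-based inclusive. Feature types outside the expected vocabulary
#' (`gene`, `exon`, `intron`, `ncRNA`, `flank`) are kept verbatim with a
#' warning.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param format `"auto"` (from extension), `"gff3"` or `"bed"`.
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `feature_type`, `gene_id`.
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  known <- c("gene", "exon", "intron", "ncRNA", "flank")
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0L) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    strand = character(), feature_type = character(),
                    gene_id = character()))
    }
    out <- tibble(
      chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]) + 1L,
      end = as.integer(df[[3]]),
      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+",
      feature_type = "gene",
      gene_id = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_
    )
  } else {
    df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0L) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    strand = character(), feature_type = character(),
                    gene_id = character()))
    }
    attrs <- as.character(df[[9]])
    gene_id <- gff3_gene_id(attrs)
    out <- tibble(
      chrom = as.character(df[[1]]),
      start = as.integer(df[[4]]),
      end = as.integer(df[[5]]),
      strand = as.character(df[[7]]),
      feature_type = as.character(df[[3]]),
      gene_id = gene_id
    )
  }
  if (any(out$start > out$end)) {
    abort_ct("interval with start > end at row %d", which(out$start > out$end)[1])
  }
  unknown <- setdiff(unique(out$feature_type), known)
  if (length(unknown) > 0L) {
    warning(sprintf("unknown feature_type(s) kept verbatim: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out
}

# Pull a per-gene identifier out of a GFF3 attributes column: prefer an
# explicit gene_id, then the Parent (child features), then ID.
gff3_gene_id <- function(attrs) {
  grab <- function(key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attrs)
    ok <- hit > 0
    out[ok] <- sub(paste0(".*", key, "="), "", regmatches(attrs, hit))
    out
  }
  gid <- grab("gene_id")
  parent <- grab("Parent")
  id <- grab("ID")
  dplyr::coalesce(gid, parent, id)
}

#' Assign CpG sites to annotated features
#'
#' Each site is matched to every feature interval that overlaps it (boundaries
#' inclusive); a site inside several features yields several rows. Sites
#' overlapping nothing are labelled `intergenic`, and additionally annotated
#' with the nearest gene within `flank_bp` (default 5000 bp, either side)
#' when one exists.
#'
#' @param sites Tibble with `chrom`, `pos`.
#' @param features Tibble as returned by [read_features()].
#' @param flank_bp Non-negative flank distance (bp) for nearest-gene
#'   annotation of intergenic sites.
#' @return A tibble with one row per site-feature assignment: `chrom`, `pos`,
#'   `feature_type`, `gene_id`, and `nearest_gene`/`nearest_dist` filled for
#'   intergenic sites.
#' @export
annotate_sites <- function(sites, features, flank_bp = 5000) {
  stopifnot(flank_bp >= 0)
  usites <- dplyr::distinct(sites, .data$chrom, .data$pos)
  if (nrow(usites) == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  feature_type = character(), gene_id = character(),
                  nearest_gene = character(), nearest_dist = integer()))
  }
  gr_sites <- GenomicRanges::GRanges(usites$chrom,
                                     IRanges::IRanges(usites$pos, usites$pos))
  if (nrow(features) > 0L) {
    gr_feat <- GenomicRanges::GRanges(features$chrom,
                                      IRanges::IRanges(features$start, features$end))
    ov <- GenomicRanges::findOverlaps(gr_sites, gr_feat)
    hit <- tibble(
      chrom = usites$chrom[S4Vectors::queryHits(ov)],
      pos = usites$pos[S4Vectors::queryHits(ov)],
      feature_type = features$feature_type[S4Vectors::subjectHits(ov)],
      gene_id = features$gene_id[S4Vectors::subjectHits(ov)],
      nearest_gene = NA_character_, nearest_dist = NA_integer_
    )
    covered <- unique(S4Vectors::queryHits(ov))
  } else {
    hit <- tibble(chrom = character(), pos = integer(),
                  feature_type = character(), gene_id = character(),
                  nearest_gene = character(), nearest_dist = integer())
    covered <- integer()
  }
  orphan_idx <- setdiff(seq_len(nrow(usites)), covered)
  if (length(orphan_idx) > 0L) {
    orphans <- usites[orphan_idx, , drop = FALSE]
    genes <- dplyr::filter(features, .data$feature_type == "gene")
    near_gene <- rep(NA_character_, nrow(orphans))
    near_dist <- rep(NA_integer_, nrow(orphans))
    if (nrow(genes) > 0L) {
      gr_o <- GenomicRanges::GRanges(orphans$chrom,
                                     IRanges::IRanges(orphans$pos, orphans$pos))
      gr_g <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
      nr <- GenomicRanges::distanceToNearest(gr_o, gr_g)
      qi <- S4Vectors::queryHits(nr)
      # GRanges distance counts the gap; the flank rule is in coordinate
      # distance (site position to nearest gene edge), hence + 1
      coord_dist <- S4Vectors::mcols(nr)$distance + 1L
      keep <- coord_dist <= flank_bp
      near_gene[qi[keep]] <- genes$gene_id[S4Vectors::subjectHits(nr)[keep]]
      near_dist[qi[keep]] <- as.integer(coord_dist[keep])
    }
    inter <- tibble(
      chrom = orphans$chrom, pos = orphans$pos,
      feature_type = "intergenic", gene_id = NA_character_,
      nearest_gene = near_gene, nearest_dist = near_dist
    )
    hit <- bind_rows(hit, inter)
  }
  arrange(hit, .data$chrom, .data$pos)
}

#' Read a tabular BLAST hit table (outfmt 6)
#'
#' Standard 12-column tab-separated BLAST output. Duplicate identical rows are
#' removed with a warning.
#'
#' @param path Path to the hit table.
#' @return Tibble with `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @export
read_blast_table <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  evalue = double(), bitscore = double()))
  }
  out <- tibble(
    query_id = as.character(df[[1]]),
    subject_id = as.character(df[[2]]),
    evalue = as.numeric(df[[11]]),
    bitscore = as.numeric(df[[12]])
  )
  if (any(out$evalue < 0)) abort_ct("negative e-value at row %d", which(out$evalue < 0)[1])
  dedup <- distinct(out)
  if (nrow(dedup) < nrow(out)) {
    warning(sprintf("%d duplicate BLAST rows removed", nrow(out) - nrow(dedup)),
            call. = FALSE)
  }
  dedup
}

#' Read a gene-to-GO mapping table
#'
#' Two-column tab-separated table of `gene_id`, `go_id` pairs; many-to-many.
#' Duplicate pairs are removed with a warning.
#'
#' @param path Path to the mapping table.
#' @return Tibble with `gene_id`, `go_id`.
#' @export
read_go_map <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0L) {
    return(tibble(gene_id = character(), go_id = character()))
  }
  out <- tibble(gene_id = as.character(df[[1]]), go_id = as.character(df[[2]]))
  dedup <- distinct(out)
  if (nrow(dedup) < nrow(out)) {
    warning(sprintf("%d duplicate GO map rows removed", nrow(out) - nrow(dedup)),
            call. = FALSE)
  }
  dedup
}
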