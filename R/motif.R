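DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Published known-motif enrichment table for TFEB-knockdown promoters
#'
#' The printed known-motif enrichment summary for promoters of genes
#' downregulated by TFEB knockdown in MDA-MB-231 cells: per motif, the
#' percent of foreground and background promoter sequences carrying the
#' motif and the resulting enrichment ratio. Shipped as package data so
#' the enrichment arithmetic can be checked against published values.
#'
#' @return Tibble: `motif`, `p_value`, `q_value_benjamini`,
#'   `n_sequences_with_motif`, `fg_pct`, `bg_pct`, `enrichment_ratio`.
#' @export
tfeb_motif_table <- function() {
  readr::read_tsv(system.file("extdata", "tfeb_knockdown_motifs.tsv",
                              package = "cyclegate"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[strsplit(toupper(s), "")[[1]]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract promoter windows around transcription start sites
#'
#' For each TSS row, extracts the promoter window spanning `upstream`
#' bases before to `downstream` bases after the TSS, both ends inclusive
#' (default 1000 and 100, giving 1101 nt), oriented in the promoter
#' direction: minus-strand windows cover `[tss - downstream,
#' tss + upstream]` on the source and are reverse-complemented. Windows
#' running off a sequence end are truncated and flagged.
#'
#' @param tss_table Data frame with columns `gene`, `seq_id`, `tss`,
#'   `strand` (`+`/`-`).
#' @param sequences Named character vector of source sequences (names =
#'   `seq_id`), or a tibble with `seq_id`/`sequence` columns as returned
#'   by [generate_promoter_set()] or [read_fasta()].
#' @param upstream,downstream Window extent in bases (inclusive bounds).
#' @param tss_one_based Whether `tss` values are 1-based coordinates
#'   (common in gene tables; default) or 0-based.
#' @return Tibble: `gene`, `seq_id`, `tss`, `strand`, `start`, `end`
#'   (0-based inclusive source coordinates), `sequence` (promoter
#'   oriented), `truncated`.
#' @export
extract_promoter_windows <- function(tss_table, sequences,
                                     upstream = 1000, downstream = 100,
                                     tss_one_based = TRUE) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$seq_id)
  }
  need <- c("gene", "seq_id", "tss", "strand")
  if (!all(need %in% names(tss_table))) {
    abort(paste0("Missing TSS columns: ",
                 paste(setdiff(need, names(tss_table)), collapse = ", ")),
          class = "cc_schema_error")
  }
  if (!all(tss_table$strand %in% c("+", "-"))) {
    abort("`strand` must be '+' or '-'.", class = "cc_schema_error")
  }
  unknown <- setdiff(tss_table$seq_id, names(sequences))
  if (length(unknown) > 0) {
    abort(paste0("Unknown sequence id(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cc_schema_error")
  }
  purrr::pmap_dfr(tss_table[need], function(gene, seq_id, tss, strand) {
    src <- sequences[[seq_id]]
    L <- nchar(src)
    tss0 <- if (tss_one_based) tss - 1 else tss
    if (tss0 < 0 || tss0 >= L) {
      abort(sprintf("TSS of %s lies outside sequence %s.", gene, seq_id),
            class = "cc_schema_error")
    }
    if (strand == "+") {
      start <- tss0 - upstream
      end <- tss0 + downstream
    } else {
      start <- tss0 - downstream
      end <- tss0 + upstream
    }
    tstart <- max(start, 0)
    tend <- min(end, L - 1)
    win <- substr(src, tstart + 1, tend + 1)
    if (strand == "-") win <- reverse_complement(win)
    was_truncated <- tstart != start || tend != end
    tibble::tibble(gene = gene, seq_id = seq_id, tss = tss,
                   strand = strand, start = tstart, end = tend,
                   sequence = win, truncated = was_truncated)
  })
}

# overlapping exact-match offsets (0-based) of `motif` in one string;
# positions containing characters outside the motif alphabet (e.g. N)
# never match because the comparison is literal
scan_one <- function(sequence, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

#' Scan promoter windows for a motif
#'
#' Exact-match, shift-by-one scan (overlapping occurrences counted) of
#' each window for the motif, reporting 0-based window offsets. The
#' default CLEAR motif `TCACGTGA` is its own reverse complement, so a
#' single-strand scan is complete; for non-palindromic motifs set
#' `both_strands = TRUE` to also scan the reverse complement, with the
#' strand reported per hit.
#'
#' @param windows Output of [extract_promoter_windows()], or any tibble
#'   with `gene` and `sequence` columns (a `seq_id` column is carried
#'   through; [generate_promoter_set()] sequences work with
#'   `gene = seq_id`).
#' @param motif DNA string over A/C/G/T.
#' @param both_strands Also scan the reverse complement.
#' @return Tibble: `gene`, `offset` (0-based, forward-window
#'   coordinates of the match start), `strand`.
#' @seealso [motif_hit_counts()]
#' @export
scan_motif <- function(windows, motif = "TCACGTGA", both_strands = FALSE) {
  if (!nzchar(motif) || !grepl("^[ACGT]+$", motif)) {
    abort("`motif` must be a non-empty string over A/C/G/T.",
          class = "cc_schema_error")
  }
  if (!"gene" %in% names(windows)) {
    windows <- dplyr::rename(windows, gene = "seq_id")
  }
  mlen <- nchar(motif)
  rc <- reverse_complement(motif)
  scan_strand <- function(m, strand) {
    purrr::map2_dfr(windows$gene, windows$sequence, function(g, s) {
      off <- scan_one(toupper(s), m)
      if (length(off) == 0) return(NULL)
      tibble::tibble(gene = g, offset = off, strand = strand)
    })
  }
  hits <- scan_strand(motif, "+")
  if (both_strands && rc != motif) {
    hits <- dplyr::bind_rows(hits, scan_strand(rc, "-"))
  }
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene = character(), offset = integer(),
                          strand = character()))
  }
  dplyr::arrange(hits, .data$gene, .data$offset)
}

#' Per-gene motif hit counts
#'
#' @param windows Windows passed to [scan_motif()] (defines the gene
#'   universe, including zero-hit genes).
#' @param hits Output of [scan_motif()].
#' @return Tibble: `gene`, `count`, `has_motif`.
#' @export
motif_hit_counts <- function(windows, hits) {
  genes <- if ("gene" %in% names(windows)) windows$gene else windows$seq_id
  tibble::tibble(gene = genes) |>
    dplyr::left_join(dplyr::count(hits, .data$gene, name = "count"),
                     by = "gene") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  has_motif = .data$count > 0)
}

#' Motif enrichment ratio
#'
#' Ratio of the foreground percentage of motif-bearing sequences to the
#' background percentage.
#'
#' @param fg_pct,bg_pct Percentages of foreground and background
#'   sequences containing the motif.
#' @return `fg_pct / bg_pct` (vectorised).
#' @export
enrichment_ratio <- function(fg_pct, bg_pct) {
  if (any(bg_pct == 0)) {
    abort("Background percentage is 0: enrichment ratio undefined.",
          class = "cc_schema_error")
  }
  fg_pct / bg_pct
}

#' Counts-based motif enrichment test
#'
#' One-sided hypergeometric test that motif-bearing sequences are
#' over-represented in the foreground: with a population of
#' `fg_total + bg_total` sequences of which `fg_with + bg_with` carry the
#' motif, `p = P[X >= fg_with]` for `X` the number of carriers in a draw
#' of size `fg_total`. Gene-level presence (at least one hit) drives the
#' counts. Vectorised over motifs; q-values are Benjamini-Hochberg across
#' the motifs tested in one call.
#'
#' @param fg_with,fg_total Foreground sequences with the motif / total.
#' @param bg_with,bg_total Background sequences with the motif / total.
#' @param motif Optional motif names.
#' @return Tibble: `motif`, `fg_with_motif`, `fg_total`, `bg_with_motif`,
#'   `bg_total`, `fg_pct`, `bg_pct`, `enrichment_ratio`, `p_value`,
#'   `q_value`.
#' @export
motif_enrichment_test <- function(fg_with, fg_total, bg_with, bg_total,
                                  motif = NULL) {
  k <- max(length(fg_with), length(fg_total), length(bg_with),
           length(bg_total))
  fg_with <- rep_len(fg_with, k); fg_total <- rep_len(fg_total, k)
  bg_with <- rep_len(bg_with, k); bg_total <- rep_len(bg_total, k)
  if (any(fg_with > fg_total) || any(bg_with > bg_total) ||
      any(c(fg_with, bg_with, fg_total, bg_total) < 0)) {
    abort("Inconsistent counts: need 0 <= with <= total.",
          class = "cc_schema_error")
  }
  p <- phyper(fg_with - 1, m = fg_with + bg_with,
              n = (fg_total + bg_total) - (fg_with + bg_with),
              k = fg_total, lower.tail = FALSE)
  tibble::tibble(
    motif = motif %||% sprintf("motif_%d", seq_len(k)),
    fg_with_motif = fg_with, fg_total = fg_total,
    bg_with_motif = bg_with, bg_total = bg_total,
    fg_pct = 100 * fg_with / fg_total,
    bg_pct = 100 * bg_with / bg_total,
    enrichment_ratio = ifelse(bg_with > 0,
                              (fg_with / fg_total) / (bg_with / bg_total),
                              NA_real_),
    p_value = p,
    q_value = bh_adjust(p))
}
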