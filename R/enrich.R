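#' Hypergeometric over-representation test of functional terms
#'
#' For each annotation term with at least one member in the selection, the
#' upper-tail hypergeometric probability P(X >= k) is computed, where k is
#' the number of selected genes annotated to the term, n the selection size,
#' K the number of background genes annotated to the term and N the
#' background size. Annotations are first restricted to background genes.
#' Following common practice for a single curated term list, p-values are by
#' default reported raw with a fixed cutoff; BH adjustment is available but
#' off by default.
#'
#' @param selected Character vector of selected gene/transcript ids; must be
#'   a subset of `background`.
#' @param background Character vector of background ids (e.g. all transcripts
#'   with reliable half-lives in both strains).
#' @param annotation Tibble with columns `term` and `gene` (optional
#'   `term_name`), e.g. from [read_gaf()] or [read_term_map()].
#' @param p_cutoff Enrichment cutoff on the (raw) p-value (default 0.05).
#' @param adjust Apply BH adjustment and threshold the adjusted values
#'   instead (default FALSE).
#' @return Tibble sorted by p-value: `term`, `term_name` (if available),
#'   `k_selected`, `n_selected`, `K_background`, `N_background`, `p_hyper`
#'   (and `q_bh` if `adjust`), `enriched`.
#' @examples
#' ann <- tibble::tibble(term = rep("T1", 10), gene = paste0("g", 1:10))
#' hypergeom_enrich(paste0("g", 1:5), paste0("g", 1:50), ann)
#' @export
hypergeom_enrich <- function(selected, background, annotation,
                             p_cutoff = 0.05, adjust = FALSE) {
  selected <- unique(selected)
  background <- unique(background)
  stray <- setdiff(selected, background)
  if (length(stray) > 0) {
    abort(sprintf("selected gene(s) not in background: %s",
                  paste(head(stray, 5), collapse = ", ")))
  }
  annotation <- as_tibble(annotation)
  stopifnot(all(c("term", "gene") %in% names(annotation)))
  annotation <- annotation |>
    filter(.data$gene %in% background) |>
    distinct(.data$term, .data$gene,
             .keep_all = "term_name" %in% names(annotation))
  if (nrow(annotation) == 0) {
    abort("annotation does not intersect the background")
  }
  N <- length(background)
  n <- length(selected)
  out <- annotation |>
    summarise(
      term_name = if ("term_name" %in% names(annotation))
        first(.data$term_name) else NA_character_,
      K_background = n_distinct(.data$gene),
      k_selected = sum(unique(.data$gene) %in% selected),
      .by = "term"
    ) |>
    filter(.data$k_selected >= 1) |>
    mutate(
      n_selected = n, N_background = N,
      p_hyper = phyper(.data$k_selected - 1, .data$K_background,
                       N - .data$K_background, n, lower.tail = FALSE)
    )
  if (adjust) {
    out <- mutate(out, q_bh = bh_adjust(.data$p_hyper),
                  enriched = .data$q_bh < p_cutoff)
  } else {
    out <- mutate(out, enriched = .data$p_hyper < p_cutoff)
  }
  arrange(out, .data$p_hyper)
}

#' Read a GAF 2.x annotation file (Biological Process rows)
#'
#' Minimal GAF reader: comment lines starting with `!` are skipped, and only
#' rows whose aspect column is `P` (Biological Process) are kept. Columns
#' used: 2 (gene id), 3 (gene symbol), 5 (term id), 9 (aspect). Term
#' names are not carried in GAF files.
#'
#' @param path Path to an (uncompressed) GAF file.
#' @param aspect Aspect code(s) to retain (default `"P"`).
#' @return Tibble with columns `gene`, `gene_symbol`, `term`.
#' @export
read_gaf <- function(path, aspect = "P") {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0) abort("GAF file contains no annotation rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9)
  if (length(short) > 0) {
    abort(sprintf("malformed GAF row(s) with < 9 columns at line(s): %s",
                  paste(head(short, 5), collapse = ", ")))
  }
  tab <- tibble(
    gene = vapply(fields, `[[`, "", 2),
    gene_symbol = vapply(fields, `[[`, "", 3),
    term = vapply(fields, `[[`, "", 5),
    aspect_code = vapply(fields, `[[`, "", 9)
  )
  tab |>
    filter(.data$aspect_code %in% aspect) |>
    select("gene", "gene_symbol", "term") |>
    distinct()
}

#' Read a two-column term-to-gene annotation table
#'
#' @param path Path to a TSV with a header; the first two columns are taken
#'   as `term` and `gene` (a third, if present, as `term_name`).
#' @return Tibble with columns `term`, `gene` (and `term_name`).
#' @export
read_term_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(tab) < 2) abort("term map needs at least two columns (term, gene)")
  names(tab)[1:2] <- c("term", "gene")
  if (ncol(tab) >= 3) names(tab)[3] <- "term_name"
  as_tibble(tab)
}
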