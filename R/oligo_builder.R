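#' Build Golden-Gate-compatible spacer cloning oligos
#'
#' For each spacer, the forward oligo prepends `AGAT` and appends `G`; the
#' reverse oligo is `GAAAC` followed by the reverse complement of the
#' spacer. When annealed, the two oligos form a duplex with a
#' `spacer_length + 1` bp paired core and 4-nt single-stranded 5'
#' extensions on each end, ready for Golden Gate insertion into a crRNA
#' expression array.
#'
#' @param spacer character vector of spacers over `{A,C,G,T}`, each of
#'   length `spacer_length`.
#' @param spacer_length expected spacer length (default 28).
#' @return `data.frame` with columns `spacer`, `forward`, `reverse`; each
#'   oligo has length `spacer_length + 5`.
#' @export
#' @examples
#' build_oligos(strrep("A", 28))
build_oligos <- function(spacer, spacer_length = 28L) {
  spacer <- check_dna(spacer, allow_n = FALSE, what = "spacer")
  if (any(nchar(spacer) != spacer_length))
    stop("all spacers must have length ", spacer_length, call. = FALSE)
  data.frame(spacer = spacer,
             forward = paste0("AGAT", spacer, "G"),
             reverse = paste0("GAAAC", reverse_complement(spacer)),
             stringsAsFactors = FALSE)
}

well_position <- function(i) {
  # row-major 96-well fill: A1..A12, B1..B12, ..., H12, then next plate
  plate <- (i - 1L) %/% 96L + 1L
  within <- (i - 1L) %% 96L
  list(plate = plate,
       well = sprintf("%s%d", LETTERS[within %/% 12L + 1L],
                      within %% 12L + 1L))
}

#' Export an oligo order sheet for an arrayed library
#'
#' One row per designed guide, assigned to 96-well plates in row-major
#' order (A1..A12, B1..B12, ...); guide 97 lands on plate 2 well A1. Oligo
#' names are `<locus_tag>_F` / `<locus_tag>_R`.
#'
#' @param report a `design_report` with at least one guide.
#' @param spacer_length spacer length used for oligo construction.
#' @return `data.frame` with columns `plate, well, locus_tag, oligo_f_name,
#'   oligo_f_seq, oligo_r_name, oligo_r_seq, spacer`.
#' @export
export_order_sheet <- function(report, spacer_length = 28L) {
  guides <- report$guides
  if (!nrow(guides)) stop("design report has no guides", call. = FALSE)
  oligos <- build_oligos(guides$spacer, spacer_length)
  pos <- lapply(seq_len(nrow(guides)), well_position)
  data.frame(plate = vapply(pos, `[[`, integer(1), "plate"),
             well = vapply(pos, `[[`, character(1), "well"),
             locus_tag = guides$locus_tag,
             oligo_f_name = paste0(guides$locus_tag, "_F"),
             oligo_f_seq = oligos$forward,
             oligo_r_name = paste0(guides$locus_tag, "_R"),
             oligo_r_seq = oligos$reverse,
             spacer = guides$spacer,
             stringsAsFactors = FALSE)
}
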