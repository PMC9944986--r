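#' MALDI intact-protein peak annotation by accurate mass
#'
#' MALDI ionization of intact proteins yields low charge states (<= 3),
#' which are hard to fragment, so peaks in an averaged MALDI spectrum are
#' assigned by accurate mass against a proteoform library built from
#' LC-MS/MS identifications.  Two modes are provided: `"monoisotopic"`
#' compares against the monoisotopic m/z, while `"apex"` adds an
#' averagine-like estimate of the isotope-envelope apex offset, since at
#' protein masses the most intense isotopologue sits several isotopes
#' above the monoisotopic peak.
#'
#' @name maldi
NULL

# Monoisotopic residue masses (Da) and the mass of water; used to compute
# neutral peptide/protein monoisotopic masses from sequence.
AA_MONO_MASS <- c(
  G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)
WATER_MONO_MASS <- 18.01056468

#' Monoisotopic mass of a peptide or protein sequence
#'
#' Sum of residue masses plus one water; fixed modifications can be added
#' as a mass delta.
#'
#' @param sequence One-letter amino-acid sequence (character scalar).
#' @param mod_mass Total mass of modifications to add, in Da.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("SGRGK")
#' @export
peptide_mono_mass <- function(sequence, mod_mass = 0) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, names(AA_MONO_MASS))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  }
  sum(AA_MONO_MASS[aa]) + WATER_MONO_MASS + mod_mass
}

#' m/z of a neutral mass at a given positive charge
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param z Positive charge (number of protons).
#' @return m/z in Th: `(mass + z * 1.007276) / z`.
#' @export
mz_from_mass <- function(mass, z) {
  stopifnot(all(z >= 1))
  (mass + z * PROTON_MASS) / z
}

#' @rdname mz_from_mass
#' @param mz Observed m/z in Th.
#' @return For `mass_from_mz`, the neutral mass in Da.
#' @export
mass_from_mz <- function(mz, z) {
  mz * z - z * PROTON_MASS
}

#' Isotope-envelope apex offset, in isotopes, for a protein mass
#'
#' A linear averagine-like heuristic: the most intense isotopologue of a
#' protein of mass M sits about `round(c * M)` isotopes above the
#' monoisotopic peak (default c = 5.5e-4 isotopes per Da).  With `c = 0`
#' apex mode degenerates to monoisotopic.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param isotopes_per_da Apex slope c.
#' @return Integer isotope count k.
#' @export
apex_offset_isotopes <- function(mass, isotopes_per_da = 5.5e-4) {
  as.integer(round(isotopes_per_da * mass))
}

#' Build a proteoform mass library from pipeline output
#'
#' @param tbl A table with an annotation column and a monoisotopic-mass
#'   column (e.g. the annotated feature groups or the final quant table).
#' @param annotation_col,mass_col Column names.
#' @return A tibble with columns `annotation` and `mono_mass`, unique by
#'   annotation (smallest mass kept on duplicates).
#' @export
proteoform_library <- function(tbl, annotation_col = "annotation",
                               mass_col = "consensus_mass") {
  lib <- tibble::tibble(annotation = tbl[[annotation_col]],
                        mono_mass = tbl[[mass_col]])
  lib <- lib[!is.na(lib$annotation) & !is.na(lib$mono_mass), ]
  lib |>
    dplyr::group_by(.data$annotation) |>
    dplyr::slice_min(.data$mono_mass, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Annotate MALDI peaks against a proteoform library
#'
#' For each peak and each charge `z <= z_max`, the predicted m/z of every
#' library entry is `(M + k * isotope_spacing + z * proton) / z`, with
#' `k = 0` in monoisotopic mode and `k = apex_offset_isotopes(M)` in apex
#' mode.  A peak is annotated with the library entry minimizing the
#' absolute ppm error, provided it is within `tol_ppm`.  The default
#' tolerance is tighter in monoisotopic mode (15 ppm) than apex mode
#' (50 ppm), because the envelope-apex estimate is approximate.
#'
#' @param peaks Peak-list tibble with columns `mz` and `intensity`
#'   (see [read_maldi_peaks()]).
#' @param library Library tibble with `annotation` and `mono_mass`
#'   (see [proteoform_library()]).
#' @param z_max Highest charge state considered.
#' @param mode `"monoisotopic"` or `"apex"`.
#' @param tol_ppm Match tolerance in ppm; default depends on `mode`.
#' @param isotopes_per_da Apex slope, see [apex_offset_isotopes()].
#' @return A tibble of hits: `mz`, `intensity`, `annotation`, `mono_mass`,
#'   `charge`, `k_isotopes`, `ppm`, `mode` -- one row per annotated peak.
#' @export
annotate_peaks <- function(peaks, library, z_max = 3,
                           mode = c("monoisotopic", "apex"), tol_ppm = NULL,
                           isotopes_per_da = 5.5e-4) {
  mode <- match.arg(mode)
  if (is.null(tol_ppm)) tol_ppm <- if (mode == "apex") 50 else 15
  empty <- tibble::tibble(mz = double(), intensity = double(),
                          annotation = character(), mono_mass = double(),
                          charge = integer(), k_isotopes = integer(),
                          ppm = double(), mode = character())
  if (nrow(library) == 0 || nrow(peaks) == 0) return(empty)
  k <- if (mode == "apex") apex_offset_isotopes(library$mono_mass, isotopes_per_da)
       else rep(0L, nrow(library))
  # predicted m/z table: one row per (entry, charge)
  pred <- do.call(rbind, lapply(seq_len(z_max), function(z) {
    data.frame(entry = seq_len(nrow(library)), charge = z, k = k,
               mz = mz_from_mass(library$mono_mass + k * ISOTOPE_SPACING_DA, z))
  }))
  hits <- lapply(seq_len(nrow(peaks)), function(i) {
    pe <- ppm_error(peaks$mz[i], pred$mz)
    best <- which.min(abs(pe))
    if (abs(pe[best]) > tol_ppm) return(NULL)
    tibble::tibble(
      mz = peaks$mz[i], intensity = peaks$intensity[i],
      annotation = library$annotation[pred$entry[best]],
      mono_mass = library$mono_mass[pred$entry[best]],
      charge = as.integer(pred$charge[best]),
      k_isotopes = as.integer(pred$k[best]),
      ppm = pe[best], mode = mode
    )
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits)
}
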