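# Monoisotopic mass arithmetic for singly-charged negative-mode ions,
# neutral-loss assignment of MS2 fragments, and Pearson-correlation feature
# clustering used to assist annotation.

# Principal-isotope atomic masses (Da), IUPAC/CODATA values.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  Cl = 34.96885268
)

# Hydrogen-atom mass used in the [M-H]- convention (no electron-mass
# correction; see electron_correction flag of adduct_mz).
.MASS_H <- .ATOMIC_MASS[["H"]]
.MASS_ELECTRON <- 0.00054857990907

#' Parse a molecular formula
#'
#' Accepts a Hill-style formula such as `"C28H52O5"` as well as the
#' underscore-decorated rendering `"C_28_H_52_O_5_"` that appears in some
#' extracted tables.  Only elements with a registered principal-isotope mass
#' (C, H, N, O, P, S, Na, Cl) are accepted.
#'
#' @param formula a single formula string.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C28H52O5")
#' parse_formula("C_24_H_40_O_4_")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  clean <- gsub("_", "", formula)
  if (!nzchar(clean)) stop("empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  tokens <- regmatches(clean, gregexpr("([A-Z][a-z]?)([0-9]*)", clean))[[1]]
  if (paste(tokens, collapse = "") != clean)
    stop("unparsable formula: ", formula)
  el <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Za-z]+", "", tokens)
  n <- ifelse(n == "", 1L, as.integer(n))
  bad <- setdiff(el, names(.ATOMIC_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(n < 1L)) stop("element counts must be positive")
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of principal-isotope atomic masses (C = 12 exactly,
#' H = 1.00782503, O = 15.99491462, ...).
#'
#' @param formula formula string (see [parse_formula()]) or a named count
#'   vector as returned by it.
#' @return monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.01056
#' monoisotopic_mass("C28H52O5")
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  bad <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * as.numeric(counts))
}

# Mass of acetic acid (HAc), used by the acetate adduct.
.MASS_HAC <- 12 * 2 + 4 * 1.00782503207 + 2 * 15.9949146196

#' m/z of a negative-mode adduct species
#'
#' Computes the m/z of singly-charged negative ions from a neutral
#' monoisotopic mass.  The default ("hydrogen-atom") convention subtracts the
#' mass of a hydrogen atom and neglects the electron mass; this is the
#' convention that reproduces published deprotonated-ion tables to within
#' their printed rounding.  Set `electron_correction = TRUE` to add the
#' electron mass to the anion.
#'
#' @param M neutral monoisotopic mass (Da), > 0.
#' @param species `"[M-H]-"` or `"[M+HAc-H]-"`.
#' @param electron_correction add m_e to the ion mass (default FALSE).
#' @return m/z in Th.
#' @examples
#' adduct_mz(468.38147, "[M-H]-")
#' @export
adduct_mz <- function(M, species = c("[M-H]-", "[M+HAc-H]-"),
                      electron_correction = FALSE) {
  species <- match.arg(species)
  stopifnot(is.numeric(M), length(M) == 1L, is.finite(M))
  if (M <= 0) stop("neutral mass must be > 0")
  mz <- switch(species,
    "[M-H]-" = M - .MASS_H,
    "[M+HAc-H]-" = M + .MASS_HAC - .MASS_H
  )
  if (electron_correction) mz <- mz + .MASS_ELECTRON
  if (mz <= 0) warning("degenerate non-positive m/z")
  mz
}

#' Relative mass deviation in ppm
#'
#' `(calculated - observed) / calculated * 1e6`; the sign convention is that
#' an observed m/z below the calculated value gives a positive deviation.
#'
#' @param calculated,observed m/z values (Th), both > 0.
#' @return deviation in ppm.
#' @export
ppm_deviation <- function(calculated, observed) {
  stopifnot(is.numeric(calculated), is.numeric(observed))
  if (any(calculated <= 0) || any(observed <= 0))
    stop("m/z values must be positive")
  (calculated - observed) / calculated * 1e6
}

#' Match a formula against an observed m/z
#'
#' Convenience wrapper combining [monoisotopic_mass()], [adduct_mz()] and
#' [ppm_deviation()].
#'
#' @param formula molecular formula of the neutral molecule.
#' @param observed observed m/z (Th).
#' @param species adduct species, see [adduct_mz()].
#' @return data.frame with calculated m/z and delta ppm.
#' @export
mass_match <- function(formula, observed, species = "[M-H]-") {
  calc <- adduct_mz(monoisotopic_mass(formula), species)
  data.frame(
    formula = if (is.character(formula)) formula else NA_character_,
    species = species,
    mz_calc = calc,
    mz_obs = observed,
    delta_ppm = ppm_deviation(calc, observed),
    stringsAsFactors = FALSE
  )
}

# Registered neutral losses (Da).
.NEUTRAL_LOSSES <- c(
  "H2O"     = 2 * 1.00782503207 + 15.9949146196,
  "CO2"     = 12 + 2 * 15.9949146196,
  "2xH2O"   = 2 * (2 * 1.00782503207 + 15.9949146196),
  "CO2+H2O" = 12 + 2 * 15.9949146196 + 2 * 1.00782503207 + 15.9949146196,
  "acetate" = .MASS_HAC
)

#' Assign neutral losses to MS2 fragments
#'
#' For each fragment m/z, tests `precursor - loss` against the registered
#' neutral losses (H2O, CO2, 2xH2O, CO2+H2O, acetic acid) and reports
#' matches within the tolerance, closest first.
#'
#' @param precursor precursor m/z (Th).
#' @param fragments numeric vector of fragment m/z values.
#' @param tolerance_mda match tolerance in mDa (default 5).
#' @return data.frame with one row per (fragment, loss) match, ordered by
#'   absolute deviation within fragment; zero rows if nothing matches.
#' @export
match_neutral_losses <- function(precursor, fragments, tolerance_mda = 5) {
  stopifnot(is.numeric(precursor), length(precursor) == 1L, precursor > 0)
  if (length(fragments) == 0)
    return(data.frame(fragment = numeric(), loss = character(),
                      loss_mass = numeric(), expected = numeric(),
                      deviation_mda = numeric(), deviation_ppm = numeric(),
                      stringsAsFactors = FALSE))
  stopifnot(all(fragments > 0))
  out <- do.call(rbind, lapply(fragments, function(f) {
    expected <- precursor - .NEUTRAL_LOSSES
    dev <- (f - expected) * 1000  # mDa
    hit <- abs(dev) <= tolerance_mda
    if (!any(hit)) return(NULL)
    d <- data.frame(
      fragment = f,
      loss = names(.NEUTRAL_LOSSES)[hit],
      loss_mass = unname(.NEUTRAL_LOSSES[hit]),
      expected = unname(expected[hit]),
      deviation_mda = unname(dev[hit]),
      deviation_ppm = unname(dev[hit] / f * 1000),
      stringsAsFactors = FALSE
    )
    d[order(abs(d$deviation_mda)), , drop = FALSE]
  }))
  if (is.null(out)) out <- match_neutral_losses(precursor, numeric(0))
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two features
#'
#' Correlation of normalized log intensities across study samples; used to
#' relate co-eluting ions during annotation.
#'
#' @param normmatrix features x samples matrix of normalized log intensities.
#' @param feature_a,feature_b feature ids (rownames of `normmatrix`).
#' @return Pearson correlation coefficient.
#' @export
correlate_features <- function(normmatrix, feature_a, feature_b) {
  stopifnot(feature_a %in% rownames(normmatrix),
            feature_b %in% rownames(normmatrix))
  a <- normmatrix[feature_a, ]
  b <- normmatrix[feature_b, ]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3) stop("need at least 3 common samples")
  if (sd(a[keep]) == 0 || sd(b[keep]) == 0)
    stop("zero-variance feature")
  cor(a[keep], b[keep])
}

#' Group features by absolute correlation
#'
#' Connected components of the graph whose edges join feature pairs with
#' `|r| >= threshold`; a light substitute for external correlation-network
#' clustering tools.
#'
#' @param normmatrix features x samples matrix.
#' @param threshold absolute-correlation edge threshold (default 0.8).
#' @return list of character vectors of feature ids (the groups).
#' @export
cluster_correlated <- function(normmatrix, threshold = 0.8) {
  p <- nrow(normmatrix)
  ids <- rownames(normmatrix)
  if (is.null(ids)) ids <- as.character(seq_len(p))
  if (p == 0) return(list())
  if (p == 1 || threshold > 1) return(as.list(ids))
  r <- suppressWarnings(cor(t(normmatrix)))
  r[!is.finite(r)] <- 0
  adj <- abs(r) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  unname(split(ids, comp$membership))
}
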