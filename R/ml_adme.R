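#' Deterministic derived-ADME formulas
#'
#' The three fixed conversions sitting between raw predicted quantities and
#' the PBPK inputs:
#' * fraction unbound in plasma from the plasma-protein-binding ratio,
#'   `fup = 1 - ppbr`;
#' * apparent clearance from distribution volume and elimination half-life,
#'   `clapp = vss * 0.693 / t_half`;
#' * gastrointestinal absorption rate from Caco-2 apparent permeability and
#'   the small-intestinal radius (1.25 cm, i.e. a 2.5 cm diameter),
#'   `gi_ka = 2 * papp / radius`.
#'
#' @param ppbr Plasma protein binding ratio, in `[0, 1)`.
#' @return `fup_from_ppbr()`: fraction unbound in `(0, 1]`.
#' @examples
#' fup_from_ppbr(0.86582)       # 0.13418
#' clapp_from_vss_halflife(100, 6.93)
#' gika_from_papp(0.948)        # 1.51647 (1/h)
#' @export
fup_from_ppbr <- function(ppbr) {
  if (!is.numeric(ppbr) || any(ppbr < 0) || any(ppbr >= 1)) {
    abort("ppbr must lie in [0, 1)")
  }
  1 - ppbr
}

#' @rdname fup_from_ppbr
#' @param vss Steady-state volume of distribution (L).
#' @param half_life Elimination half-life (h).
#' @return `clapp_from_vss_halflife()`: apparent clearance (L/h).
#' @export
clapp_from_vss_halflife <- function(vss, half_life) {
  if (!is.numeric(vss) || any(vss <= 0)) abort("vss must be positive")
  if (!is.numeric(half_life) || any(half_life <= 0)) {
    abort("half_life must be positive")
  }
  vss * 0.693 / half_life
}

#' @rdname fup_from_ppbr
#' @param papp Caco-2 apparent permeability (cm/h).
#' @param radius Small-intestinal radius (cm, default 1.25).
#' @return `gika_from_papp()`: absorption rate constant (1/h).
#' @export
gika_from_papp <- function(papp, radius = 1.25) {
  if (!is.numeric(papp) || any(papp <= 0)) abort("papp must be positive")
  if (!is.numeric(radius) || any(radius <= 0)) abort("radius must be positive")
  2 * papp / radius
}
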