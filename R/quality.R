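#' Total colour difference in CIELAB space
#'
#' Euclidean distance between two CIELAB colours — the usual deltaE
#' measure of overall colour change on drying.  The reference is an
#' explicit argument (typically the fresh sample measured alongside the
#' dried one).
#'
#' @param sample,reference [color_record()] objects.
#' @return colour difference in CIELAB units (>= 0).
#' @examples
#' delta_e(color_record(54, 13, 10), color_record(50, 10, 10))  # 5
#' @export
delta_e <- function(sample, reference) {
  stopifnot(inherits(sample, "color_record"),
            inherits(reference, "color_record"))
  sqrt((sample$L_star - reference$L_star)^2 +
       (sample$a_star - reference$a_star)^2 +
       (sample$b_star - reference$b_star)^2)
}

#' Browning index from CIELAB coordinates
#'
#' Chromatic indicator of non-enzymatic (Maillard) browning:
#'
#'   X  = (a* + 1.75 L*) / (c L* + a* - 3.012 b*)
#'   BI = 100 (X - 0.31) / 0.17
#'
#' The denominator constant `c` defaults to 6.645; much of the browning
#' literature uses 5.645 instead, so the constant is exposed as an
#' argument.  BI is zero exactly at X = 0.31 and is affine (strictly
#' increasing) in X.
#'
#' @param color a [color_record()].
#' @param bi_denominator_constant multiplier of L* in the denominator
#'   of X (default 6.645).
#' @return named numeric vector `c(x_chromatic, bi)`.
#' @export
browning_index <- function(color, bi_denominator_constant = 6.645) {
  stopifnot(inherits(color, "color_record"))
  den <- bi_denominator_constant * color$L_star + color$a_star -
    3.012 * color$b_star
  if (abs(den) < 1e-12)
    stop("chromatic coordinate X undefined: zero denominator",
         call. = FALSE)
  x <- (color$a_star + 1.75 * color$L_star) / den
  c(x_chromatic = x, bi = 100 * (x - 0.31) / 0.17)
}

#' Shrinkage ratio
#'
#' Fractional volume loss on drying, 1 - V_dried / V_fresh.  Invariant
#' under rescaling both volumes; warns if the dried volume exceeds the
#' fresh one (physically suspect but not impossible for puffed tissue).
#'
#' @param v_fresh,v_dried slice volumes before and after drying, cm^3 (> 0).
#' @return shrinkage fraction (< 1).
#' @examples
#' shrinkage_ratio(10, 7.5)  # 0.25
#' @export
shrinkage_ratio <- function(v_fresh, v_dried) {
  if (any(v_fresh <= 0) || any(v_dried <= 0))
    stop("volumes must be strictly positive", call. = FALSE)
  if (any(v_dried > v_fresh))
    warning("dried volume exceeds fresh volume")
  1 - v_dried / v_fresh
}

#' Rehydration ratio
#'
#' Rehydrated-to-dried mass ratio, a reconstitution-quality measure;
#' values well above 1 indicate a porous, readily rewetted structure.
#'
#' @param m_rehydrated,m_dried sample masses after and before
#'   rehydration, g (> 0).
#' @return mass ratio.
#' @examples
#' rehydration_ratio(17.5, 5)  # 3.5
#' @export
rehydration_ratio <- function(m_rehydrated, m_dried) {
  if (any(m_rehydrated <= 0) || any(m_dried <= 0))
    stop("masses must be strictly positive", call. = FALSE)
  m_rehydrated / m_dried
}

#' Classify water activity for shelf stability
#'
#' Water activity is an instrument reading, never computed here; this
#' classifies it against the conventional microbial-stability threshold:
#' below 0.6 (strictly) the product is considered shelf-stable.
#'
#' @param aw water activity in \[0, 1\]; vectorised.
#' @return character vector, `"shelf_stable"` or `"at_risk"`.
#' @examples
#' validate_water_activity(c(0.412, 0.962, 0.6))
#' @export
validate_water_activity <- function(aw) {
  if (any(!is.finite(aw)) || any(aw < 0 | aw > 1))
    stop("water activity must lie in [0, 1]", call. = FALSE)
  ifelse(aw < 0.6, "shelf_stable", "at_risk")
}

#' Assemble a quality record for one condition
#'
#' Computes every quality index from the raw colour and volume/mass
#' measurements of one dried sample against its fresh reference.
#'
#' @param condition_id label.
#' @param color dried-sample [color_record()].
#' @param reference fresh-sample [color_record()].
#' @param vm a [volume_mass_record()].
#' @param bi_denominator_constant passed to [browning_index()].
#' @return one-row data.frame: condition_id, delta_e, x_chromatic, bi,
#'   sr, rr, aw, aw_class.
#' @export
quality_record <- function(condition_id, color, reference, vm,
                           bi_denominator_constant = 6.645) {
  stopifnot(inherits(vm, "volume_mass_record"))
  b <- browning_index(color, bi_denominator_constant)
  aw <- vm$water_activity
  data.frame(
    condition_id = as.character(condition_id),
    delta_e = delta_e(color, reference),
    x_chromatic = unname(b["x_chromatic"]),
    bi = unname(b["bi"]),
    sr = shrinkage_ratio(vm$volume_fresh, vm$volume_dried),
    rr = rehydration_ratio(vm$mass_rehydrated, vm$mass_dried),
    aw = aw,
    aw_class = if (is.na(aw)) NA_character_ else validate_water_activity(aw),
    stringsAsFactors = FALSE)
}
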