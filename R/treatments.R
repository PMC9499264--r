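#' Measured growth traits
#'
#' The nine per-plant traits recorded in a trial: organ lengths, fresh and
#' dry weights, the derived dry-biomass percentages, and the SPAD
#' chlorophyll index.
#'
#' @return Character vector of canonical trait names.
#' @export
trait_levels <- function() {
  c("root_length_cm", "shoot_length_cm",
    "root_fw_g", "shoot_fw_g",
    "root_dw_g", "shoot_dw_g",
    "root_dry_biomass_pct", "shoot_dry_biomass_pct",
    "spad")
}

#' Canonical treatment labels for the two packaged trials
#'
#' The wheat trial crossed char amendment, two microbial consortia (MC-B,
#' MC-C, delivered by seed coating or on functionalized char) and AMF
#' inoculum into twelve conditions; the maize trial used char delivery only,
#' eight conditions.
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return Character vector of treatment labels in table order.
#' @export
treatment_labels <- function(crop = c("wheat", "maize")) {
  crop <- match.arg(crop)
  if (crop == "wheat") {
    c("Control", "Char", "AMF", "Char_AMF",
      "MC-B", "MC-C", "MC-B_AMF", "MC-C_AMF",
      "Char_MC-B", "Char_MC-C", "Char_MC-B_AMF", "Char_MC-C_AMF")
  } else {
    c("Control", "Char", "AMF", "Char_AMF",
      "Char_MC-B", "Char_MC-B_AMF", "Char_MC-C", "Char_MC-C_AMF")
  }
}

#' Parse a treatment label into its design components
#'
#' Labels are underscore-joined tokens out of `Char`, `MC-B`/`MC-C` and
#' `AMF`; `Control` is the empty combination. The delivery route is implied:
#' a consortium present together with char is delivered on functionalized
#' char, a consortium without char is seed-coated, and treatments without a
#' consortium have no delivery vehicle.
#'
#' @param label Treatment label, e.g. `"Char_MC-C_AMF"`.
#' @return A list with elements `char_present`, `consortium` (`"none"`,
#'   `"MC-B"` or `"MC-C"`), `amf_present`, `delivery` (`"none"`,
#'   `"seed_coating"` or `"functionalized_char"`) and the canonical `label`.
#' @export
parse_treatment <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label == "Control") {
    tokens <- character(0)
  } else {
    tokens <- strsplit(label, "_", fixed = TRUE)[[1L]]
  }
  known <- c("Char", "MC-B", "MC-C", "AMF")
  bad <- setdiff(tokens, known)
  if (length(bad) > 0L) {
    stop("unknown treatment token(s): ", paste(bad, collapse = ", "),
         " in label '", label, "'")
  }
  char_present <- "Char" %in% tokens
  amf_present <- "AMF" %in% tokens
  mc <- intersect(c("MC-B", "MC-C"), tokens)
  if (length(mc) > 1L) stop("label '", label, "' names two consortia")
  consortium <- if (length(mc) == 1L) mc else "none"
  delivery <- if (consortium == "none") {
    "none"
  } else if (char_present) {
    "functionalized_char"
  } else {
    "seed_coating"
  }
  out <- list(char_present = char_present, consortium = consortium,
              amf_present = amf_present, delivery = delivery)
  out$label <- format_treatment(out)
  if (out$label != label) {
    stop("label '", label, "' is not in canonical token order; expected '",
         out$label, "'")
  }
  out
}

#' Format treatment components into the canonical label
#'
#' Inverse of [parse_treatment()]: token order is Char, consortium, AMF.
#'
#' @param x A list with `char_present`, `consortium`, `amf_present`.
#' @return Canonical label string.
#' @export
format_treatment <- function(x) {
  tokens <- character(0)
  if (isTRUE(x$char_present)) tokens <- c(tokens, "Char")
  if (!is.null(x$consortium) && x$consortium != "none") {
    tokens <- c(tokens, x$consortium)
  }
  if (isTRUE(x$amf_present)) tokens <- c(tokens, "AMF")
  if (length(tokens) == 0L) "Control" else paste(tokens, collapse = "_")
}
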