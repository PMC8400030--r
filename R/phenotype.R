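#' Classify a marker profile into a denitrification phenotype
#'
#' The denitrification chain reduces nitrate stepwise,
#' NO3- -> NO2- -> NO -> N2O -> N2, through the four marker enzymes Nar,
#' Nir, Nor and Nos. From the presence/absence of those enzymes this derives:
#'
#' * `status`: `denitrifier` iff at least `min_enzymes` (default 1) of the
#'   four are present — the working definition used for genome surveys, even
#'   though single-enzyme species may not be denitrifiers under stricter
#'   physiological definitions (raise `min_enzymes` for a stricter call);
#' * `completeness`: `non` (0 enzymes), `partial` (1–3), `complete` (all 4);
#' * `end_product`: the product of the most downstream enzyme present
#'   (Nar -> nitrite, Nir -> NO, Nor -> N2O, Nos -> N2; empty -> `none`);
#' * `emitter`: `NO_emitter` / `N2O_emitter` when the pathway theoretically
#'   ends in one of the two gases, `N2_reducer` whenever Nos is present,
#'   otherwise `none`;
#' * `consecutive`: whether the present enzymes occupy a contiguous interval
#'   of the chain (an empty profile is consecutive by convention);
#' * `rule_derived`: `TRUE` for enzyme combinations whose end product follows
#'   from the most-downstream rule but is not among the combinations usually
#'   enumerated in surveys (e.g. Nar+Nos).
#'
#' @param nar,nir,nor,nos logical presence flags for the four enzymes.
#' @param species optional species label.
#' @param min_enzymes minimum number of enzymes for denitrifier status.
#' @return one-row data frame with columns `species`, `status`,
#'   `completeness`, `end_product`, `emitter`, `consecutive`, `n_enzymes`,
#'   `rule_derived`.
#' @examples
#' classify_profile(nar = TRUE, nir = TRUE, nor = FALSE, nos = FALSE)
#' @export
classify_profile <- function(nar, nir, nor, nos,
                             species = NA_character_, min_enzymes = 1) {
  flags <- c(nar = nar, nir = nir, nor = nor, nos = nos)
  stopifnot(is.logical(flags), !anyNA(flags), min_enzymes >= 1)
  n <- sum(flags)
  ep <- end_product(nar, nir, nor, nos)
  emitter <- if (nos) "N2_reducer"
             else if (ep == "NO") "NO_emitter"
             else if (ep == "N2O") "N2O_emitter"
             else "none"
  listed <- list(
    none    = character(0),
    nitrite = "nar",                      # Nar-only: nitrite accumulates
    NO      = list(c("nar", "nir"), "nir"),
    N2O     = list(c("nar", "nir", "nor"), c("nar", "nor"),
                   c("nir", "nor"), "nor"),
    N2      = list(c("nar", "nir", "nor", "nos"),
                   c("nir", "nor", "nos"), c("nor", "nos")))
  present <- names(flags)[flags]
  enumerated <- any(vapply(listed[[ep]],
                           function(s) setequal(s, present), logical(1))) ||
    ep %in% c("none", "nitrite")
  data.frame(species = species,
             status = if (n >= min_enzymes) "denitrifier"
                      else "non_denitrifier",
             completeness = if (n == 0) "non" else if (n == 4) "complete"
                            else "partial",
             end_product = ep, emitter = emitter,
             consecutive = is_consecutive(nar, nir, nor, nos),
             n_enzymes = as.integer(n),
             rule_derived = !enumerated,
             stringsAsFactors = FALSE)
}

#' Theoretical end product of a marker profile
#'
#' The product of the most downstream enzyme present in the chain
#' Nar (nitrite) -> Nir (NO) -> Nor (N2O) -> Nos (N2); `"none"` for an empty
#' profile.
#'
#' @inheritParams classify_profile
#' @return one of `"none"`, `"nitrite"`, `"NO"`, `"N2O"`, `"N2"`.
#' @export
end_product <- function(nar, nir, nor, nos) {
  if (nos) "N2" else if (nor) "N2O" else if (nir) "NO"
  else if (nar) "nitrite" else "none"
}

#' Are the present enzymes consecutive steps of the pathway?
#'
#' `TRUE` iff the present enzymes occupy a contiguous interval of the ordered
#' chain Nar, Nir, Nor, Nos (empty profile: `TRUE` by convention).
#'
#' @inheritParams classify_profile
#' @return logical flag.
#' @export
is_consecutive <- function(nar, nir, nor, nos) {
  w <- which(c(nar, nir, nor, nos))
  length(w) == 0 || identical(w, seq(min(w), max(w)))
}

#' Classify every profile in a presence matrix
#'
#' Row-wise [classify_profile()] over a profile table.
#'
#' @param profiles data frame of profiles as from [build_profiles()] /
#'   [read_profiles()].
#' @param min_enzymes passed to [classify_profile()].
#' @return data frame of phenotype calls, one row per species, plus the
#'   `nir_type` column carried through for reporting.
#' @export
classify_profiles <- function(profiles, min_enzymes = 1) {
  profiles <- validate_profiles(profiles)
  calls <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(k)
    classify_profile(profiles$nar[k], profiles$nir[k], profiles$nor[k],
                     profiles$nos[k], species = profiles$species[k],
                     min_enzymes = min_enzymes)))
  if (is.null(calls))
    calls <- classify_profile(TRUE, TRUE, TRUE, TRUE)[0, ]
  calls$nir_type <- profiles$nir_type
  calls
}
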