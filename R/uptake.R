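#' Percent-of-control uptake
#'
#' Converts a raw Mitoxantrone uptake rate measured in the presence of a
#' competing substrate to a percentage of the control rate (Mitoxantrone
#' alone), rounded half-up to an integer as the published uptake tables
#' print it.
#'
#' @param raw_rate uptake rate with the competing substrate; strictly
#'   positive.
#' @param control_rate uptake rate of Mitoxantrone alone; strictly positive.
#' @return integer percent, `round_half_up(100 * raw_rate / control_rate)`.
#' @examples
#' percent_uptake(29.64, 23.71)  # 125
#' percent_uptake(23.58, 25.92)  # 91
#' @export
percent_uptake <- function(raw_rate, control_rate) {
  if (any(!is.finite(raw_rate)) || any(!is.finite(control_rate)) ||
      any(raw_rate <= 0) || any(control_rate <= 0))
    stop("uptake rates must be finite and strictly positive")
  as.integer(floor(100 * raw_rate / control_rate + 0.5))
}

#' Apparent permeability (Papp)
#'
#' Transwell apparent permeability: the linear appearance rate of drug on
#' the receiving side divided by the insert area times the initial donor
#' concentration, `Papp = (dQ/dt) / (A * D0)`.
#'
#' @param dQdt linear appearance rate (amount/time).
#' @param A cross-sectional area of the insert; strictly positive.
#' @param D0 initial donor-side concentration; strictly positive.
#' @return apparent permeability (cm/sec when the inputs use cm and sec).
#' @export
apparent_permeability <- function(dQdt, A, D0) {
  if (any(!is.finite(A)) || any(!is.finite(D0)) || any(A <= 0) || any(D0 <= 0))
    stop("A and D0 must be finite and strictly positive")
  dQdt / (A * D0)
}

#' Construct a response set for one polymorph
#'
#' Holds per-compound uptake rates for one BCRP-482 polymorph: the raw rate,
#' the percent-of-control as printed in the source table, and a recomputed
#' percent. Rows whose printed percent differs from the recomputed one by
#' more than one integer point (rounding slack for two-decimal raw rates)
#' are flagged as inconsistent, never silently corrected.
#'
#' @param polymorph one of `"482R"`, `"482G"`, `"482T"`.
#' @param control_rate the Mitoxantrone-alone uptake rate; strictly positive.
#' @param compound_id character vector of compound ids.
#' @param raw_rate numeric vector of raw uptake rates, positive.
#' @param percent printed integer percents; `NULL` to recompute them.
#' @param role optional roles (`"training"`/`"test"`) per compound.
#' @return a `response_set`: data frame with columns `compound_id`, `role`,
#'   `raw_rate`, `percent`, `percent_recomputed`, `inconsistent`, plus
#'   attributes `polymorph` and `control_rate`.
#' @export
response_set <- function(polymorph, control_rate, compound_id, raw_rate,
                         percent = NULL, role = NA_character_) {
  polymorph <- match.arg(polymorph, POLYMORPHS)
  stopifnot(is.finite(control_rate), control_rate > 0,
            length(compound_id) == length(raw_rate))
  if (anyDuplicated(compound_id))
    stop("duplicate compound id in response set")
  rec <- percent_uptake(raw_rate, control_rate)
  if (is.null(percent)) percent <- rec
  out <- data.frame(
    compound_id = as.character(compound_id),
    role = rep_len(as.character(role), length(compound_id)),
    raw_rate = as.numeric(raw_rate),
    percent = as.integer(percent),
    percent_recomputed = rec,
    inconsistent = abs(as.integer(percent) - rec) > 1L,
    stringsAsFactors = FALSE
  )
  structure(out, polymorph = polymorph, control_rate = control_rate,
            class = c("response_set", "data.frame"))
}

#' Load the bundled BCRP uptake dataset
#'
#' Returns the published Mitoxantrone uptake rates for 25 experimental sets
#' (the Mitoxantrone control plus 17 training substrates, and 7 test
#' substrates) across the three BCRP-482 polymorphs, together with the
#' train/test assignment. Raw rates are stored unit-agnostically ("uptake
#' rate, source units"); only ratios are used downstream. Printed percent
#' values are kept verbatim; cells whose printed percent disagrees with
#' recomputation from the raw rate and the polymorph control by more than
#' one point carry an `inconsistent` flag. Ketoconazole was measured in both
#' the training and the test block; the test-set replicate gets the id
#' `ketoconazole_test` to keep ids unique.
#'
#' @return list with elements `responses` (named list of three
#'   [response_set()] objects, one per polymorph), `assignment` (named
#'   character vector id -> role) and `compounds` (data frame of id, name,
#'   role).
#' @export
load_uptake_fixture <- function() {
  path <- system.file("extdata", "bcrp_uptake.csv", package = "hqsar",
                      mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id <- compound_id(d$compound)
  dup <- duplicated(id)
  id[dup] <- paste0(id[dup], "_", d$role[dup])
  ctrl <- d$compound == "Mitoxantrone"
  responses <- lapply(POLYMORPHS, function(p) {
    raw <- d[[paste0("raw_", p)]]
    response_set(p, control_rate = raw[ctrl], compound_id = id,
                 raw_rate = raw, percent = d[[paste0("pct_", p)]],
                 role = d$role)
  })
  names(responses) <- POLYMORPHS
  list(
    responses = responses,
    assignment = stats::setNames(d$role, id),
    compounds = data.frame(id = id, name = d$compound, role = d$role,
                           stringsAsFactors = FALSE)
  )
}

#' Load the bundled descriptor-class catalogue
#'
#' The 26 named molecular descriptors used for BCRP-482 model building,
#' each tagged with its class (8 constitutional, 3 thermodynamic,
#' 3 electrostatic, 12 quantum-chemical).
#'
#' @return data frame with columns `name` and `dclass`.
#' @export
load_descriptor_catalogue <- function() {
  path <- system.file("extdata", "descriptor_classes.csv", package = "hqsar",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
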