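# Generalized-model descriptions matching the three packaged scenarios.

#' Generalized model for a single population with observed births
#'
#' One population `A` with a gain (`births`, observed as a rate channel,
#' dependence on `A` left free) and a loss (`deaths`, inferred by
#' balancing the observed births against the population change, and
#' assumed linear in `A` -- the coefficient may drift with time). The
#' eigenvalue estimate is the birth slope minus the death slope.
#'
#' @return a [gm_model()].
#' @export
allee_model <- function() {
  gm_model(
    variables = "A",
    processes = list(
      gm_process("births", "gain", "A", depends_on = "A",
                 observability = "observed",
                 assumptions = list(A = "free")),
      gm_process("deaths", "loss", "A", depends_on = "A",
                 observability = "inferred_by_balance",
                 assumptions = list(A = "linear"), drifting = TRUE)),
    time_mode = "continuous")
}

#' Generalized model for the annually observed fishery
#'
#' Two variables (adult piscivore `P`, planktivore `F`) in discrete time.
#' The piscivore balance has recruitment (inferred by balance, assumed
#' linear in `P`, free in `F`), natural mortality of known linear form
#' (`mP`), and the observed catch as an exogenous loss. The planktivore
#' balance has a known constant refuge influx (`fin`), growth of known
#' logistic form (`rF`, `KF`), and predation by adults (inferred by
#' balance, assumed linear in `P`, free in `F`). The reproduction rate
#' `rP` is carried as a known constant for stability-based parameter
#' screening. Note the deliberate mismatch with the simulator, which has
#' a hidden juvenile stage and intra-annual dynamics.
#'
#' @param mP,rP,fin,rF,KF known rate constants.
#' @return a [gm_model()].
#' @export
fishery_model <- function(mP = 0.1, rP = 0.9, fin = 0.05, rF = 1, KF = 1) {
  gm_model(
    variables = c("P", "F"),
    processes = list(
      gm_process("recruitment", "gain", "P", depends_on = c("P", "F"),
                 observability = "inferred_by_balance",
                 assumptions = list(P = "linear", F = "free")),
      gm_process("natural_mortality", "loss", "P", depends_on = "P",
                 observability = "known_form",
                 form = list(kind = "linear", of = "P", rate = "mP")),
      gm_process("catch", "loss", "P", depends_on = character(),
                 observability = "observed", drifting = TRUE),
      gm_process("influx", "gain", "F", depends_on = character(),
                 observability = "known_form",
                 form = list(kind = "constant", value = "fin")),
      gm_process("growth", "gain", "F", depends_on = "F",
                 observability = "known_form",
                 form = list(kind = "logistic", of = "F", r = "rF", K = "KF")),
      gm_process("predation", "loss", "F", depends_on = c("F", "P"),
                 observability = "inferred_by_balance",
                 assumptions = list(P = "linear", F = "free"))),
    time_mode = "discrete",
    known_constants = list(mP = mP, rP = rP, fin = fin, rF = rF, KF = KF))
}

#' Generalized model for the tri-trophic food chain
#'
#' Producer `X`, predator `Y`, top predator `Z` in continuous time; the
#' observed rate channel is the top-predator mortality. The top intake is
#' inferred from the `Z` balance (linear in `Z`, free in `Y`); the
#' predator's assimilation is inferred from the `Y` balance (linear in
#' `Y`, free in `X`) after accounting for the predation loss -- the top
#' intake divided by the conversion efficiency `e2` -- and a known linear
#' mortality `mY`; the producer's production is inferred from the `X`
#' balance (free in `X`) after removing the grazing loss, the
#' assimilation divided by `e1`. Only the efficiencies and the predator
#' mortality need to be known, the kind of information available from
#' metabolic studies.
#'
#' @param e1,e2 conversion efficiencies.
#' @param mY intermediate predator mortality (1/yr).
#' @return a [gm_model()].
#' @export
food_chain_model <- function(e1 = 0.6, e2 = 0.7, mY = 0.08) {
  gm_model(
    variables = c("X", "Y", "Z"),
    processes = list(
      gm_process("production", "gain", "X", depends_on = "X",
                 observability = "inferred_by_balance",
                 assumptions = list(X = "free")),
      gm_process("grazing", "loss", "X", depends_on = c("X", "Y"),
                 observability = "known_form",
                 form = list(kind = "scaled_process", process = "assimilation",
                             scale = "e1", op = "divide")),
      gm_process("assimilation", "gain", "Y", depends_on = c("X", "Y"),
                 observability = "inferred_by_balance",
                 assumptions = list(Y = "linear", X = "free")),
      gm_process("predation_loss", "loss", "Y", depends_on = c("Y", "Z"),
                 observability = "known_form",
                 form = list(kind = "scaled_process", process = "top_intake",
                             scale = "e2", op = "divide")),
      gm_process("mortality_Y", "loss", "Y", depends_on = "Y",
                 observability = "known_form",
                 form = list(kind = "linear", of = "Y", rate = "mY")),
      gm_process("top_intake", "gain", "Z", depends_on = c("Y", "Z"),
                 observability = "inferred_by_balance",
                 assumptions = list(Z = "linear", Y = "free")),
      gm_process("top_mortality", "loss", "Z", depends_on = "Z",
                 observability = "observed",
                 assumptions = list(Z = "linear"), drifting = TRUE)),
    time_mode = "continuous",
    known_constants = list(e1 = e1, e2 = e2, mY = mY))
}
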