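#' Construct a carbon/nitrogen limitation scenario
#'
#' Three canonical scenarios plus a C/N-ratio sweep describe how forced
#' bicarbonate uptake rises while nitrate either stays constant (s1, s3,
#' cn_sweep) or ramps up once carbon passes a threshold (s2); s1 opens the
#' DMSP release and nitrate-storage demands, s3 instead routes excess
#' carbon into TAG/chrysolaminarin storage.
#'
#' @param scenario "s1", "s2", "s3" or "cn_sweep".
#' @param carbonRxn,nitrogenRxn exchange reaction ids (defaults fit the toy
#'   model, [makeToyModel()]).
#' @param carbonGrid strictly increasing forced-uptake magnitudes (mM).
#' @param nitrogenBase constant nitrate uptake (mM).
#' @param nitrogenRule "constant" or "ramp_after_threshold".
#' @param rampThreshold carbon level (mM) at which the nitrate ramp starts.
#' @param rampStep nitrate increment (mM) per grid step once ramping.
#' @param openDemands,closedDemands demand reaction ids to open / close.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(scenario = c("s1", "s2", "s3", "cn_sweep"),
                         carbonRxn = "EX_hco3_e", nitrogenRxn = "EX_no3_e",
                         carbonGrid = seq(0.6, 6, by = 0.6),
                         nitrogenBase = 0.5,
                         nitrogenRule = NULL,
                         rampThreshold = NA_real_, rampStep = NA_real_,
                         openDemands = NULL, closedDemands = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(nitrogenRule))
    nitrogenRule <- if (scenario == "s2") "ramp_after_threshold" else "constant"
  if (scenario == "s2" && is.na(rampThreshold)) rampThreshold <- 3.0
  if (scenario == "s2" && is.na(rampStep)) rampStep <- 0.1
  if (is.null(openDemands)) {
    openDemands <- switch(scenario,
      s1 = c("DM_dmsp_c", "DM_no3_c"),
      s2 = c("DM_dmsp_c", "DM_no3_c"),
      s3 = c("DM_no3_c", "DM_tag_c", "DM_chryso_c"),
      cn_sweep = c("DM_dmsp_c", "DM_no3_c"))
  }
  if (is.null(closedDemands)) {
    closedDemands <- switch(scenario,
      s1 = c("DM_tag_c", "DM_chryso_c"),
      s2 = c("DM_tag_c", "DM_chryso_c"),
      s3 = "DM_dmsp_c",
      cn_sweep = c("DM_tag_c", "DM_chryso_c"))
  }
  new("ScenarioSpec", scenario = scenario, carbonRxn = carbonRxn,
      nitrogenRxn = nitrogenRxn, carbonGrid = as.numeric(carbonGrid),
      nitrogenBase = nitrogenBase, nitrogenRule = nitrogenRule,
      rampThreshold = rampThreshold, rampStep = rampStep,
      openDemands = as.character(openDemands),
      closedDemands = as.character(closedDemands))
}

#' Run a limitation scenario over its carbon grid
#'
#' At each grid point the carbon exchange is forced to the stated uptake
#' (equality bounds, uptake negative), nitrate is set per the nitrogen rule,
#' the listed demand reactions are opened (`[0, 1000]`) or closed
#' (`[0, 0]`), and the model is solved parsimoniously. The limitation
#' breakpoint is the last grid point at which biomass still increased: the
#' smallest carbon uptake at which growth stops responding to added carbon,
#' resolved to one grid step.
#'
#' @param model a [MetabolicModel-class].
#' @param spec a [ScenarioSpec-class].
#' @param tolFlat biomass increase below which the sweep counts as flat.
#' @param solver LP backend.
#' @return a [ScenarioResult-class]; `steps` has one row per grid point
#'   with columns `carbon_uptake`, `nitrogen_uptake`, `cn_ratio`, `biomass`
#'   and one flux column per tracked demand reaction.
#' @examples
#' res <- runScenario(makeToyModel(), scenarioSpec("s1"))
#' res@breakpointCNRatio   # 6: the toy biomass consumes 6 C per N
#' @export
runScenario <- function(model, spec, tolFlat = 1e-8, solver = simplexSolver) {
  stopifnot(is(model, "MetabolicModel"), is(spec, "ScenarioSpec"))
  validObject(spec)
  rxns <- reactionIds(model)
  for (r in c(spec@carbonRxn, spec@nitrogenRxn))
    if (!r %in% rxns) stop("scenario reaction not in model: ", r)
  demands <- c(spec@openDemands, spec@closedDemands)
  missing <- setdiff(demands, rxns)
  if (length(missing))
    stop("scenario demand reaction(s) not in model: ",
         paste(missing, collapse = ", "))

  nRamped <- 0L
  rows <- vector("list", length(spec@carbonGrid))
  for (i in seq_along(spec@carbonGrid)) {
    uC <- spec@carbonGrid[i]
    if (spec@nitrogenRule == "ramp_after_threshold" && uC >= spec@rampThreshold)
      nRamped <- nRamped + 1L
    uN <- spec@nitrogenBase +
      if (spec@nitrogenRule == "ramp_after_threshold") nRamped * spec@rampStep else 0
    cs <- constraintSet(
      c(spec@carbonRxn, spec@nitrogenRxn, spec@openDemands, spec@closedDemands),
      c(-uC, -uN, rep(0, length(spec@openDemands)),
        rep(0, length(spec@closedDemands))),
      c(-uC, -uN, rep(1000, length(spec@openDemands)),
        rep(0, length(spec@closedDemands))))
    sol <- parsimoniousFBA(applyConstraints(model, cs), solver = solver)
    if (sol@status != "optimal")
      stop("scenario step ", i, " (carbon uptake ", uC, ") is ", sol@status)
    dm <- setNames(as.list(sol@fluxes[demands]), demands)
    rows[[i]] <- data.frame(carbon_uptake = uC, nitrogen_uptake = uN,
                            cn_ratio = uC / uN,
                            biomass = sol@objectiveValue,
                            dm, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  steps <- do.call(rbind, rows)
  bp <- NA_real_; bpRatio <- NA_real_
  if (nrow(steps) >= 2L) {
    inc <- diff(steps$biomass)
    flat <- which(inc < tolFlat)
    if (length(flat)) {
      bp <- steps$carbon_uptake[flat[1]]      # last point of increase
      bpRatio <- bp / steps$nitrogen_uptake[flat[1]]
    }
  }
  new("ScenarioResult", steps = steps, breakpointCarbon = bp,
      breakpointCNRatio = bpRatio)
}

#' Sweep the carbon/nitrogen ratio and locate the limitation breakpoint
#'
#' An s1-style sweep reported against the C/N ratio (carbon uptake divided
#' by nitrogen uptake); biomass grows while carbon limits and stagnates
#' once nitrogen does, and `breakpointCNRatio` marks the switch.
#'
#' @inheritParams runScenario
#' @return a [ScenarioResult-class].
#' @export
cnSweep <- function(model, spec, tolFlat = 1e-8, solver = simplexSolver) {
  runScenario(model, spec, tolFlat = tolFlat, solver = solver)
}
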