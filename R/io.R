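# File interchange: tidy CSV artifacts, PEtab-style tables, SBML Level
# 3 model export/import, JSON configuration and run manifests.
#
# CSV dialect: UTF-8, comma separator, '.' decimal, header row; times in
# model units (the day conversion constant is recorded in manifests).

#' Write a trajectory as tidy CSV
#'
#' Long format: `time, species, value, condition_id`.
#'
#' @param traj A `cbsd_trajectory`.
#' @param path Output file.
#' @param condition_id Label recorded in the file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, condition_id = "condition") {
  df <- data.frame(
    time = rep(traj$time, ncol(traj$state)),
    species = rep(colnames(traj$state), each = length(traj$time)),
    value = as.vector(traj$state),
    condition_id = condition_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV back into a matrix form
#' @param path CSV written by [write_trajectory_csv()].
#' @return List with `time`, `state`, `condition_id`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  sp <- unique(df$species)
  tt <- sort(unique(df$time))
  st <- sapply(sp, function(s) {
    df$value[df$species == s][order(df$time[df$species == s])]
  })
  list(time = tt, state = st, condition_id = df$condition_id[1])
}

#' Write a bifurcation diagram as CSV pair
#'
#' `path` receives the branch points (`branch_id, param_value,
#' species..., stable`); the fold table goes to `folds_path`.
#'
#' @param diagram A `cbsd_diagram`.
#' @param path Branch CSV path.
#' @param folds_path Folds CSV path (default derived from `path`).
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path,
                              folds_path = sub("\\.csv$", "_folds.csv",
                                               path)) {
  rows <- do.call(rbind, lapply(seq_along(diagram$branches), function(i) {
    pts <- diagram$branches[[i]]$points
    cbind(branch_id = i, param_value = pts$param,
          pts[, setdiff(colnames(pts), c("param", "det"))])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  f <- diagram$folds
  if (!is.null(f) && nrow(f)) {
    names(f)[names(f) == "param"] <- "param_value"
    utils::write.csv(f, folds_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a population summary CSV
#' @param pop A `cbsd_population`.
#' @param path Output CSV.
#' @param per_cell Also write per-cell endpoints next to `path`?
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path, per_cell = FALSE) {
  df <- data.frame(
    condition = paste0("TGF0=", pop$condition$TGF0,
                       if (pop$condition$knockdown) "+kd" else ""),
    start = pop$start_label %||% "custom",
    n_cells = pop$n_cells,
    frac_E = pop$fractions[["E"]], frac_P = pop$fractions[["P"]],
    frac_M = pop$fractions[["M"]],
    n_failed = pop$n_failed %||% 0,
    omega = pop$omega, t_end = pop$t_end, seed = pop$seed %||% NA)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (per_cell) {
    utils::write.csv(pop$per_cell,
                     sub("\\.csv$", "_cells.csv", path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter table (PEtab parameter-table conventions)
#'
#' Flat TSV with columns `parameterId, value, unit, lowerBound,
#' upperBound, parameterScale, estimate`.
#'
#' @param params Parameter vector.
#' @param path Output `.tsv` (or `.json`, chosen by extension).
#' @param estimate Names of parameters flagged as estimated.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path,
                                  estimate = dlc1_free_parameters()) {
  unit <- ifelse(grepl("^n", names(params)), "dimensionless",
          ifelse(grepl("^J", names(params)), "uM",
          ifelse(grepl("_tl$|^kd_|^kd_dm$", names(params)), "1/h", "uM/h")))
  df <- data.frame(parameterId = names(params),
                   value = unname(params), unit = unit,
                   lowerBound = 1e-5, upperBound = 100,
                   parameterScale = "log10",
                   estimate = as.integer(names(params) %in% estimate))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a parameter table written by [write_parameter_table()]
#' @param path `.tsv` or `.json` parameter table.
#' @return Named parameter vector (validated).
#' @export
read_parameter_table <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.delim(path)
  }
  p <- stats::setNames(df$value, df$parameterId)
  validate_params(p[names(cbsd_params())])
}

# ---------------------------------------------------------------------
# SBML Level 3 export / import

mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mathml_times <- function(...) {
  paste0("<apply><times/>", paste0(..., collapse = ""), "</apply>")
}
mathml_hill_act <- function(x_ml, J, n) {
  # x^n / (J^n + x^n)
  pw <- function(b) paste0("<apply><power/>", b, mathml_ci(n), "</apply>")
  paste0("<apply><divide/>", pw(x_ml),
         "<apply><plus/>", pw(mathml_ci(J)), pw(x_ml), "</apply></apply>")
}
mathml_hill_rep <- function(x_ml, J, n) {
  pw <- function(b) paste0("<apply><power/>", b, mathml_ci(n), "</apply>")
  paste0("<apply><divide/>", pw(mathml_ci(J)),
         "<apply><plus/>", pw(mathml_ci(J)), pw(x_ml), "</apply></apply>")
}
mathml_total_tgf <- function() {
  paste0("<apply><plus/>", mathml_ci("TGFb_auto"),
         mathml_times(mathml_ci("tgf_unit_scale"), mathml_ci("TGF0")),
         "</apply>")
}

# MathML for each reaction of the CBSD network, keyed by reaction name
reaction_mathml <- function(r_name) {
  Tt <- mathml_total_tgf()
  kd <- mathml_ci("knockdown_factor")
  switch(r_name,
    snail1_transcription_basal = mathml_ci("k0_s"),
    snail1_transcription_tgf = mathml_times(
      mathml_ci("ks1"), mathml_hill_act(Tt, "J1s", "n1s")),
    snail1_transcription_dlc1 = mathml_times(
      mathml_ci("ks2"), mathml_hill_act(mathml_ci("DLC1"), "J2s", "n2s")),
    snail1_degradation = mathml_times(mathml_ci("kd_s"),
                                      mathml_ci("snail1_mRNA")),
    SNAIL1_translation = mathml_times(
      mathml_ci("kS_tl"), mathml_ci("snail1_mRNA"),
      mathml_hill_rep(mathml_ci("miR34"), "JS_34", "nS_34")),
    SNAIL1_degradation = mathml_times(mathml_ci("kd_S"), mathml_ci("SNAIL1")),
    miR34_production_basal = mathml_ci("k0_3"),
    miR34_production_regulated = mathml_times(
      mathml_ci("k3"),
      mathml_two_rep("SNAIL1", "J1_3", "n1_3", "ZEB1", "J2_3", "n2_3")),
    miR34_degradation = mathml_times(mathml_ci("kd_3"), mathml_ci("miR34")),
    zeb1_transcription_basal = mathml_ci("k0_z"),
    zeb1_transcription_snail1 = mathml_times(
      mathml_ci("kz"), mathml_hill_act(mathml_ci("SNAIL1"), "Jz", "nz")),
    zeb1_degradation = mathml_times(mathml_ci("kd_z"),
                                    mathml_ci("zeb1_mRNA")),
    ZEB1_translation = mathml_times(
      mathml_ci("kZ_tl"), mathml_ci("zeb1_mRNA"),
      mathml_hill_rep(mathml_ci("miR200"), "JZ_200", "nZ_200")),
    ZEB1_degradation = mathml_times(mathml_ci("kd_Z"), mathml_ci("ZEB1")),
    miR200_production_basal = mathml_ci("k0_2"),
    miR200_production_regulated = mathml_times(
      mathml_ci("k2"),
      mathml_two_rep("SNAIL1", "J1_2", "n1_2", "ZEB1", "J2_2", "n2_2")),
    miR200_degradation = mathml_times(mathml_ci("kd_2"), mathml_ci("miR200")),
    Ecad_production_snail1_gate = mathml_times(
      mathml_ci("kE1"), mathml_hill_rep(mathml_ci("SNAIL1"), "J1E", "n1E")),
    Ecad_production_zeb1_gate = mathml_times(
      mathml_ci("kE2"), mathml_hill_rep(mathml_ci("ZEB1"), "J2E", "n2E")),
    Ecad_degradation = mathml_times(mathml_ci("kd_E"), mathml_ci("Ecad")),
    Ncad_production_snail1 = mathml_times(
      mathml_ci("kN1"), mathml_hill_act(mathml_ci("SNAIL1"), "J1N", "n1N")),
    Ncad_production_zeb1 = mathml_times(
      mathml_ci("kN2"), mathml_hill_act(mathml_ci("ZEB1"), "J2N", "n2N")),
    Ncad_degradation = mathml_times(mathml_ci("kd_N"), mathml_ci("Ncad")),
    TGFb_auto_production_basal = mathml_ci("k0_T"),
    TGFb_auto_production_regulated = mathml_times(
      mathml_ci("kT"), mathml_hill_rep(mathml_ci("miR200"), "JT", "nT")),
    TGFb_auto_turnover = mathml_times(mathml_ci("kd_T"),
                                      mathml_ci("TGFb_auto")),
    dlc1_transcription_basal = mathml_times(kd, mathml_ci("k0_d")),
    dlc1_transcription_tgf = mathml_times(
      kd, mathml_ci("kd1"), mathml_hill_act(Tt, "J1d", "n1d")),
    dlc1_transcription_zeb1 = mathml_times(
      kd, mathml_ci("kd2"), mathml_hill_act(mathml_ci("ZEB1"),
                                            "J2d", "n2d")),
    dlc1_degradation = mathml_times(mathml_ci("kd_dm"),
                                    mathml_ci("dlc1_mRNA")),
    DLC1_translation = mathml_times(mathml_ci("kD_tl"),
                                    mathml_ci("dlc1_mRNA")),
    DLC1_degradation = mathml_times(mathml_ci("kd_D"), mathml_ci("DLC1")),
    stop("no MathML template for reaction ", r_name))
}

mathml_two_rep <- function(x1, J1, n1, x2, J2, n2) {
  pw <- function(num, den, n) {
    paste0("<apply><power/><apply><divide/>", mathml_ci(num),
           mathml_ci(den), "</apply>", mathml_ci(n), "</apply>")
  }
  paste0("<apply><divide/><cn> 1 </cn><apply><plus/><cn> 1 </cn>",
         pw(x1, J1, n1), pw(x2, J2, n2), "</apply></apply>")
}

#' Export the CBSD model as SBML Level 3
#'
#' Writes an SBML L3V2 document with the eleven species, all kinetic
#' parameters (plus `TGF0` and `knockdown_factor` as input parameters)
#' and one reaction per elementary process with its kinetic law in
#' MathML. The document round-trips through [read_sbml()].
#'
#' @param params Parameter vector.
#' @param cond Condition (encoded in `TGF0` / `knockdown_factor`).
#' @param path Output `.xml` file.
#' @param initial Initial concentrations (default the epithelial start).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(params, cond, path,
                       initial = default_initial_state(params)) {
  net <- build_reaction_network(params, cond)
  esc <- function(x) x
  species_xml <- paste0(vapply(cbsd_species(), function(sp) {
    sprintf(paste0(
      '      <species id="%s" compartment="cell" ',
      'initialConcentration="%.10g" hasOnlySubstanceUnits="false" ',
      'boundaryCondition="false" constant="false"/>'),
      sp, initial[[sp]])
  }, ""), collapse = "\n")
  par_all <- c(params, TGF0 = cond$TGF0,
               knockdown_factor = knockdown_factor(params, cond))
  params_xml <- paste0(vapply(names(par_all), function(pn) {
    sprintf('      <parameter id="%s" value="%.10g" constant="true"/>',
            pn, par_all[[pn]])
  }, ""), collapse = "\n")
  reactions_xml <- paste0(vapply(net$reactions, function(r) {
    sp <- names(r$stoich)[r$stoich != 0]
    role <- if (r$stoich[[sp]] > 0) "listOfProducts" else "listOfReactants"
    refs <- sprintf('        <%s><speciesReference species="%s" stoichiometry="1" constant="true"/></%s>',
                    role, sp, role)
    sprintf(paste0(
      '      <reaction id="%s" reversible="false">\n%s\n',
      '        <kineticLaw>\n',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
      '            %s\n          </math>\n        </kineticLaw>\n',
      '      </reaction>'),
      r$name, refs, esc(reaction_mathml(r$name)))
  }, ""), collapse = "\n")
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="CBSD" name="Cascading bistable switch EMT model with DLC1" substanceUnits="micromole" timeUnits="hour" volumeUnits="litre">
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
%s
    </listOfSpecies>
    <listOfParameters>
%s
    </listOfParameters>
    <listOfReactions>
%s
    </listOfReactions>
  </model>
</sbml>
', species_xml, params_xml, reactions_xml)
  writeLines(doc, path)
  invisible(path)
}

#' Import an SBML file written by [write_sbml()]
#'
#' Reads species initial concentrations, parameter values and the
#' reaction list, and reconstructs the parameter vector, condition and
#' network. Only documents following this package's export layout are
#' supported.
#'
#' @param path SBML file.
#' @return List with `params`, `cond`, `initial`, `network`,
#'   `reaction_ids`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  snodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(snodes, "initialConcentration")),
    xml2::xml_attr(snodes, "id"))
  rids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//reaction"), "id")
  params <- validate_params(pv[names(cbsd_params())])
  kf <- pv[["knockdown_factor"]]
  cond <- cbsd_condition(pv[["TGF0"]], kf < 1,
                         if (kf < 1) 1 - kf else 0)
  list(params = params, cond = cond,
       initial = cbsd_state(values = init[cbsd_species()]),
       network = build_reaction_network(params, cond),
       reaction_ids = rids)
}

# ---------------------------------------------------------------------
# PEtab-style problem export / import

#' Export a calibration problem as PEtab-style tables
#'
#' Writes `model.xml` (SBML), `parameters.tsv`, `conditions.tsv`,
#' `observables.tsv` and `measurements.tsv` into `dir`.
#'
#' @param dataset A `cbsd_dataset`.
#' @param params Parameter vector (nominal values).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_petab <- function(dataset, params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sbml(params, cbsd_condition(), file.path(dir, "model.xml"))
  write_parameter_table(params, file.path(dir, "parameters.tsv"))
  conds <- attr(dataset, "conditions")
  utils::write.table(
    data.frame(conditionId = conds$condition, TGF0 = conds$TGF0,
               knockdown = as.integer(conds$knockdown)),
    file.path(dir, "conditions.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  obs <- unique(dataset$observable)
  utils::write.table(
    data.frame(observableId = paste0("obs_", obs),
               observableFormula = obs,
               noiseFormula = paste0("noiseParameter1_obs_", obs)),
    file.path(dir, "observables.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(observableId = paste0("obs_", dataset$observable),
               simulationConditionId = dataset$condition,
               time = dataset$time,
               measurement = dataset$value,
               noiseParameters = dataset$sd),
    file.path(dir, "measurements.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' Import PEtab-style tables into a calibration dataset
#'
#' @param dir Directory written by [write_petab()] (or following the
#'   same layout).
#' @return List with `dataset` (a `cbsd_dataset`) and `params` (from
#'   `parameters.tsv`, when present).
#' @export
read_petab <- function(dir) {
  meas <- utils::read.delim(file.path(dir, "measurements.tsv"))
  conds <- utils::read.delim(file.path(dir, "conditions.tsv"))
  ds <- data.frame(
    time = meas$time,
    observable = sub("^obs_", "", meas$observableId),
    value = meas$measurement,
    sd = meas$noiseParameters,
    condition = meas$simulationConditionId,
    stringsAsFactors = FALSE)
  attr(ds, "conditions") <- data.frame(
    condition = conds$conditionId, TGF0 = conds$TGF0,
    knockdown = as.logical(conds$knockdown), stringsAsFactors = FALSE)
  class(ds) <- c("cbsd_dataset", "data.frame")
  params <- NULL
  pfile <- file.path(dir, "parameters.tsv")
  if (file.exists(pfile)) {
    params <- tryCatch(read_parameter_table(pfile), error = function(e) NULL)
  }
  list(dataset = ds, params = params)
}

#' Write a run manifest
#'
#' Records the configuration digest, seeds, day-conversion constant and
#' package version of a reproducible run.
#'
#' @param path Output JSON path.
#' @param config Named list of run settings.
#' @param seeds Named or plain integer vector of seeds used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = integer(0)) {
  man <- list(
    package = "cbsd",
    version = as.character(utils::packageVersion("cbsd")),
    time_units_per_day = time_units_per_day(),
    seeds = as.list(seeds),
    config = config,
    config_digest = digest_params(unlist(lapply(config, function(x) {
      if (is.numeric(x)) sum(x) else nchar(paste(x, collapse = ""))
    })) %||% numeric(0)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
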