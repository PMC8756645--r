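#' Specification of the toy fermentation model
#'
#' The toy network converts glucose and xylose to pyruvate units, which
#' feed biomass (with a phosphate requirement), citrate synthesis (with a
#' CO2-releasing overhead), or respiration. Citrate leaves through a
#' dedicated exporter; phosphate enters through an external exchange and
#' an internal-store exchange. The planted scenario mirrors a
#' citrate-producing timepoint where the unconstrained citrate optimum is
#' about 2.6x the constrained (in vivo-like) output: the biomass
#' stoichiometry is derived from the target fluxes so that, with sugar,
#' phosphate and biomass exchanges pinned to their targets, the maximal
#' citrate flux equals `unconstrained_citrate` exactly, and constraining
#' the planted bottleneck(s) to `constrained_citrate` reproduces the
#' in vivo-like flux.
#'
#' @param glucose_flux,xylose_flux,phosphate_flux,biomass_flux target
#'   exchange fluxes at the focal timepoint (uptake negative).
#' @param constrained_citrate in vivo-like citrate output flux.
#' @param unconstrained_citrate citrate optimum of the unregulated model.
#' @param bottlenecks planted bottleneck reactions, a subset of
#'   `c("CITT", "CITSYN")` (citrate exporter / citrate synthesis).
#' @param n_decoy_transcripts unassociated transcripts added to the
#'   expression tables (seeded).
#' @return list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(glucose_flux = -0.4392,
                           xylose_flux = -0.0647,
                           phosphate_flux = -0.0019,
                           biomass_flux = 0.0195,
                           constrained_citrate = 0.12,
                           unconstrained_citrate = 0.3159,
                           bottlenecks = "CITT",
                           n_decoy_transcripts = 10L) {
  if (!all(bottlenecks %in% c("CITT", "CITSYN")))
    stop("bottlenecks must be among CITT, CITSYN")
  carbon_in <- 6 * abs(glucose_flux) + 5 * abs(xylose_flux)
  spare <- carbon_in - 9 * unconstrained_citrate
  if (spare <= 0)
    stop("unconstrained_citrate not reachable from the sugar inputs")
  structure(list(glucose_flux = glucose_flux, xylose_flux = xylose_flux,
                 phosphate_flux = phosphate_flux, biomass_flux = biomass_flux,
                 constrained_citrate = constrained_citrate,
                 unconstrained_citrate = unconstrained_citrate,
                 bottlenecks = bottlenecks,
                 n_decoy_transcripts = as.integer(n_decoy_transcripts),
                 # biomass consumes pyruvate (3 C each); coefficient chosen so
                 # all carbon not in biomass can reach citrate (9 C per unit)
                 pyr_coef = spare / (3 * biomass_flux),
                 pi_coef = abs(phosphate_flux) / biomass_flux),
            class = "toy_model_spec")
}

#' Build the toy metabolic model with planted ground truth
#'
#' Deterministic for a given spec and seed (the seed only drives the
#' expression-table noise, recorded here for provenance). The returned
#' ground-truth record stores the target fluxes, the unconstrained and
#' constrained citrate optima, the planted bottlenecks with their
#' reference fluxes, the per-metabolite carbon counts used by the
#' carbon-closure checks, and the exchange map for the dynamic simulator.
#'
#' @param spec a `toy_model_spec`.
#' @param seed integer seed recorded in the ground truth.
#' @return list of class `toy_fixture` with elements `model` and `truth`.
#' @export
make_toy_model <- function(spec = toy_model_spec(), seed = 1L) {
  pc <- formatC(spec$pyr_coef, digits = 15, format = "g")
  qc <- formatC(spec$pi_coef, digits = 15, format = "g")
  big <- default_bound()
  rx <- function(id, name, eq, lb, ub, assoc = "", sub = "") {
    data.frame(reaction_id = id, name = name, equation = eq,
               lower_bound = lb, upper_bound = ub, association = assoc,
               subsystem = sub, stringsAsFactors = FALSE)
  }
  reactions <- rbind(
    rx("EX_GLC", "Glucose exchange", "GLC <==>", -big, 0, sub = "exchange"),
    rx("EX_XYL", "Xylose exchange", "XYL <==>", -big, 0, sub = "exchange"),
    rx("EX_PIE", "External phosphate exchange", "PIE <==>", -big, 0,
       sub = "exchange"),
    rx("EX_PI", "Internal phosphate exchange", "PI <==>", -big, big,
       sub = "exchange"),
    rx("EX_CIT", "Citrate exchange", "CIT <==>", 0, big, sub = "exchange"),
    rx("EX_CO2", "Carbon dioxide exchange", "CO2 <==>", 0, big,
       sub = "exchange"),
    rx("EX_O2", "Oxygen exchange", "O2 <==>", -big, 0, sub = "exchange"),
    rx("GLCT", "Glucose transport", "GLC -> HEX", 0, 10, "tGLCT1",
       "transport"),
    rx("XYLT", "Xylose transport", "XYL -> PEN", 0, 10,
       "tXYLT1 OR tXYLT2", "transport"),
    rx("PIT", "Phosphate transport", "PIE -> PI", 0, 10, "tPIT1",
       "transport"),
    rx("GLYC", "Glycolysis (lumped)", "HEX -> 2*PYR", 0, 10,
       "tGLYC1 AND tGLYC2", "glycolysis"),
    rx("PPP", "Pentose catabolism (lumped)", "3*PEN -> 5*PYR", 0, 10,
       "tPPP1", "pentose"),
    rx("CITSYN", "Citrate synthesis (lumped)", "3*PYR -> CITC + 3*CO2",
       0, 10, "tCITS1", "tca"),
    rx("CITT", "Citrate exporter", "CITC -> CIT", 0, 10,
       "tCITT1 OR tCITT2", "transport"),
    rx("RESP", "Respiration (lumped)", "PYR + 2.5*O2 -> 3*CO2", 0, 10,
       "tRESP1", "respiration"),
    rx("ACC", "Pyruvate decarboxylation", "PYR -> ACE + CO2", 0, 10,
       "tACC1", "overflow"),
    rx("ACR", "Acetate respiration", "ACE + 2*O2 -> 2*CO2", 0, 10,
       "tACR1", "overflow"),
    rx("ALD", "Hexose overflow route", "HEX -> 2*ACE + 2*CO2", 0, 10,
       "tALD1 AND tALD2", "overflow"),
    rx("BIO", "Biomass", paste0(pc, "*PYR + ", qc, "*PI ->"), 0, 10,
       "", "biomass")
  )
  model <- new_metabolic_model(reactions, id = "toy_citrate",
                               objective_id = "BIO", biomass_id = "BIO")

  targets <- c(EX_PI = spec$phosphate_flux,
               EX_GLC = spec$glucose_flux,
               EX_XYL = spec$xylose_flux,
               BIO = spec$biomass_flux,
               EX_CIT = spec$constrained_citrate)
  # reference fluxes at the flanking timepoints (T1-like growth phase,
  # T3-like xylose phase); planted so the constraint limit of a bottleneck
  # (larger reference / fold change 6) sits below the constrained target
  ref <- data.frame(
    reaction_id = c("CITT", "CITSYN", "ACC", "ALD", "XYLT", "PIT"),
    flux_t1 = c(0.60, 0.60, 0.10, 0.12, 0.0718, 0.15),
    flux_t3 = c(spec$unconstrained_citrate, 0.35, 0.06, 0.08, 0.1936, 0.0),
    stringsAsFactors = FALSE)

  planted_fold <- 6
  decoys <- data.frame(
    reaction_id = c("ACC", "ALD", "XYLT"),
    direction = c("constrain", "constrain", "force"),
    fold = c(2.5, 3, 2.8),
    stringsAsFactors = FALSE)

  truth <- list(
    seed = as.integer(seed),
    spec = spec,
    targets = targets,
    citrate_id = "EX_CIT",
    unconstrained_citrate = spec$unconstrained_citrate,
    constrained_citrate = spec$constrained_citrate,
    bottlenecks = spec$bottlenecks,
    bottleneck_fold = planted_fold,
    decoys = decoys,
    eligible = sort(c(spec$bottlenecks, decoys$reaction_id)),
    reference_fluxes = ref,
    carbon = c(GLC = 6, XYL = 5, PIE = 0, PI = 0, HEX = 6, PEN = 5,
               PYR = 3, CITC = 6, CIT = 6, CO2 = 1, ACE = 2, O2 = 0),
    biomass_carbon = 3 * spec$pyr_coef,
    exchange_map = list(glucose = "EX_GLC", xylose = "EX_XYL",
                        phosphate_ext = "EX_PIE", phosphate_store = "EX_PI",
                        citrate = "EX_CIT", co2 = "EX_CO2"))
  structure(list(model = model, truth = truth), class = "toy_fixture")
}

# TPM at the later timepoint giving an exact reaction-level fold change
# under the 0.5 pseudocount
tpm_for_fold <- function(early, fold) (early + 0.5) / fold - 0.5

#' Expression and differential-expression tables with planted events
#'
#' Builds three timepoint profiles (T1 growth phase, T2/T3 citrate
#' production) and a transcript-level DE table such that the
#' reaction-level eligibility computed by [eligible_reactions()] equals
#' the planted set exactly: each bottleneck is down-regulated 6-fold at
#' T1 to T2 with a tiny q-value, decoy events (two down, one up) are
#' planted on non-limiting reactions, and the remaining reactions receive
#' only sub-threshold jitter (seeded).
#'
#' @param fixture a `toy_fixture` from [make_toy_model()].
#' @param seed RNG seed for the jitter and decoy transcripts.
#' @return list with `profiles` (named TPM vectors for T1/T2/T3) and `de`
#'   (transcript-level table).
#' @export
make_expression_tables <- function(fixture, seed = fixture$truth$seed) {
  truth <- fixture$truth
  with_seed(seed, {
    t1 <- c(tGLCT1 = 200, tXYLT1 = 18, tXYLT2 = 12, tPIT1 = 80,
            tGLYC1 = 150, tGLYC2 = 90, tPPP1 = 70, tCITS1 = 110,
            tCITT1 = 72, tCITT2 = 48, tRESP1 = 130, tACC1 = 60,
            tALD1 = 45, tALD2 = 88, tACR1 = 40)
    t2 <- t1
    t3 <- t1

    # planted bottleneck(s): reaction-level 6-fold down at T1 -> T2
    fold <- truth$bottleneck_fold
    if ("CITT" %in% truth$bottlenecks) {
      tot2 <- tpm_for_fold(t1[["tCITT1"]] + t1[["tCITT2"]], fold)
      t2[["tCITT1"]] <- 0.6 * tot2
      t2[["tCITT2"]] <- 0.4 * tot2
      t3[["tCITT1"]] <- 0.62 * tot2
      t3[["tCITT2"]] <- 0.41 * tot2
    }
    if ("CITSYN" %in% truth$bottlenecks) {
      t2[["tCITS1"]] <- tpm_for_fold(t1[["tCITS1"]], fold)
      t3[["tCITS1"]] <- t2[["tCITS1"]] * 1.05
    }
    # decoy events
    t2[["tACC1"]] <- tpm_for_fold(t1[["tACC1"]], 2.5)          # down, T1-T2
    t3[["tACC1"]] <- t2[["tACC1"]] * 1.1
    ald2 <- tpm_for_fold(min(t1[["tALD1"]], t1[["tALD2"]]), 3) # AND: min
    t2[["tALD1"]] <- ald2
    t3[["tALD1"]] <- ald2 * 0.95
    xt3 <- tpm_for_fold(t2[["tXYLT1"]] + t2[["tXYLT2"]], 1 / 2.8) # up, T2-T3
    t3[["tXYLT1"]] <- 0.6 * xt3
    t3[["tXYLT2"]] <- 0.4 * xt3
    # sub-threshold event (fold 1.5 down, significant q, below fold cut)
    t2[["tPIT1"]] <- tpm_for_fold(t1[["tPIT1"]], 1.5)
    t3[["tPIT1"]] <- t2[["tPIT1"]]
    # seeded jitter on untouched housekeeping transcripts (< 10%)
    stable <- c("tGLCT1", "tGLYC1", "tGLYC2", "tPPP1", "tRESP1", "tACR1",
                if (!"CITSYN" %in% truth$bottlenecks) "tCITS1")
    t2[stable] <- t1[stable] * runif(length(stable), 0.95, 1.05)
    t3[stable] <- t1[stable] * runif(length(stable), 0.95, 1.05)
    # decoy transcripts without reaction associations
    nd <- truth$spec$n_decoy_transcripts
    if (nd > 0) {
      dn <- sprintf("tDECOY%02d", seq_len(nd))
      dv <- round(runif(nd, 2, 300), 2)
      t1[dn] <- dv
      t2[dn] <- dv * runif(nd, 0.3, 3)
      t3[dn] <- dv * runif(nd, 0.3, 3)
    }
    profiles <- list(T1 = t1, T2 = t2, T3 = t3)

    l2 <- function(a, b) log2((b + 0.5) / (a + 0.5))
    qs <- setNames(rep(0.5, length(t1)), names(t1))
    qs[c("tCITT1", "tCITT2")] <- 1e-8
    qs[c("tCITS1")] <- if ("CITSYN" %in% truth$bottlenecks) 1e-6 else 0.5
    qs[c("tACC1")] <- 1e-4
    qs[c("tALD1", "tALD2")] <- 1e-5
    qs[c("tXYLT1", "tXYLT2")] <- 1e-6
    qs[c("tPIT1")] <- 0.004
    de <- rbind(
      data.frame(transcript_id = names(t1), comparison = "T1-T2",
                 log2FC = l2(t1, t2)[names(t1)], q_value = qs,
                 stringsAsFactors = FALSE),
      data.frame(transcript_id = names(t1), comparison = "T2-T3",
                 log2FC = l2(t2, t3)[names(t1)],
                 q_value = ifelse(names(t1) %in% c("tXYLT1", "tXYLT2"),
                                  1e-6, 0.5),
                 stringsAsFactors = FALSE),
      data.frame(transcript_id = names(t1), comparison = "T1-T3",
                 log2FC = l2(t1, t3)[names(t1)], q_value = qs,
                 stringsAsFactors = FALSE))
    rownames(de) <- NULL
    list(profiles = profiles, de = de)
  })
}

#' Default initial culture state for the toy fermentation
#'
#' Mixed-sugar batch start: 30 mM glucose, 20 mM xylose, 1 mM external
#' phosphate, no citrate, 1 g/L biomass, empty internal store.
#'
#' @return a `culture_state`.
#' @export
toy_initial_state <- function() {
  culture_state(biomass = 1.0,
                concentrations = c(glucose = 30, xylose = 20,
                                   phosphate_ext = 1.0, citrate = 0, co2 = 0),
                pi_store = 0)
}

#' Reference trajectory at a fine Euler step
#'
#' Runs the batch simulation at a small `dt` to serve as the integration
#' reference that coarser-step runs are compared against.
#'
#' @param fixture a `toy_fixture`.
#' @param params a `kinetic_parameters`.
#' @param init initial `culture_state`.
#' @param duration simulated hours.
#' @param dt fine Euler step (default 1e-3 h).
#' @param ... passed to [simulate_batch()].
#' @return a `dfba_trajectory`.
#' @export
make_reference_trajectory <- function(fixture, params = kinetic_parameters(),
                                      init = toy_initial_state(),
                                      duration = 5, dt = 1e-3, ...) {
  simulate_batch(fixture$model, params, init, duration, dt = dt,
                 exchange_map = fixture$truth$exchange_map, ...)
}

#' Write all fixture files into a directory
#'
#' Emits the model TSV, wide expression TSV, DE TSV, reference-flux TSV
#' and a ground-truth JSON, all regenerable from (spec, seed).
#'
#' @param fixture a `toy_fixture`.
#' @param dir output directory (created if missing).
#' @param seed seed for the expression tables.
#' @return the directory, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir, seed = fixture$truth$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_tsv(fixture$model, file.path(dir, "model.tsv"))
  expr <- make_expression_tables(fixture, seed = seed)
  write_expression_tsv(expr$profiles, file.path(dir, "expression.tsv"))
  write_de_tsv(expr$de, file.path(dir, "de.tsv"))
  write.table(fixture$truth$reference_fluxes,
              file.path(dir, "reference_fluxes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- fixture$truth
  jsonlite::write_json(
    list(seed = tr$seed, targets = as.list(tr$targets),
         citrate_id = tr$citrate_id,
         unconstrained_citrate = tr$unconstrained_citrate,
         constrained_citrate = tr$constrained_citrate,
         bottlenecks = tr$bottlenecks, eligible = tr$eligible,
         carbon = as.list(tr$carbon), biomass_carbon = tr$biomass_carbon,
         exchange_map = tr$exchange_map),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
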