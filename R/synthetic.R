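## Synthetic test bed: a hand-authored, frozen toy network of central T cell
## metabolism (three compartments e/c/m), three cell-type expression
## archetypes, and a default uptake medium. The network is deliberately
## small (~85 reactions) but carries every pathway the analyses probe:
## glycolysis with two hexokinase isozymes, lactate fermentation, oxidative
## PPP plus a ribose salvage route to ribose-5-phosphate, pyruvate oxidation
## and a lumped TCA/electron chain (P/O 2.5), glutaminolysis, CPT1-gated
## fatty-acid oxidation, glutathione synthesis and recycling, ascorbate/
## glutaredoxin superoxide detoxification, superoxide dismutases, an NADPH
## oxidase, heme uptake with heme oxygenase (CO/biliverdin/Fe2+ release), a
## multi-precursor biomass reaction and an ATP demand. Every internal
## reaction balances carbon and oxygen exactly (formulas are authored pool
## formulas, fractional for the biomass pseudo-species).

.toyMetabolites <- function() {
  ## id, compartment, formula, charge
  m <- rbind(
    c("glc_e", "e", "C6H12O6", 0), c("glc_c", "c", "C6H12O6", 0),
    c("g6p_c", "c", "C6H13O9P", 0),
    c("ru5p_c", "c", "C5H11O8P", 0), c("r5p_c", "c", "C5H11O8P", 0),
    c("rib_e", "e", "C5H10O5", 0), c("rib_c", "c", "C5H10O5", 0),
    c("pyr_c", "c", "C3H4O3", 0), c("pyr_m", "m", "C3H4O3", 0),
    c("lac_c", "c", "C3H6O3", 0), c("lac_e", "e", "C3H6O3", 0),
    c("ac_m", "m", "C2H4O2", 0), c("ac_c", "c", "C2H4O2", 0),
    c("akg_m", "m", "C5H6O5", 0),
    c("gln_e", "e", "C5H10N2O3", 0), c("gln_c", "c", "C5H10N2O3", 0),
    c("gln_m", "m", "C5H10N2O3", 0),
    c("glu_m", "m", "C5H9NO4", 0), c("glu_c", "c", "C5H9NO4", 0),
    c("aa_e", "e", "C4H9NO3", 0), c("aa_c", "c", "C4H9NO3", 0),
    c("aax_c", "c", "C4H9NO3", 0),
    c("fa_e", "e", "C8H16O2", 0), c("fa_c", "c", "C8H16O2", 0),
    c("fa_m", "m", "C8H16O2", 0), c("lip_c", "c", "C8H16O2", 0),
    c("nad_c", "c", "C21H27N7O14P2", -1), c("nadh_c", "c", "C21H28N7O14P2", -2),
    c("nad_m", "m", "C21H27N7O14P2", -1), c("nadh_m", "m", "C21H28N7O14P2", -2),
    c("nadp_c", "c", "C21H28N7O17P3", -3), c("nadph_c", "c", "C21H29N7O17P3", -4),
    c("atp_c", "c", "C10H16N5O13P3", -4), c("adp_c", "c", "C10H15N5O10P2", -3),
    c("atp_m", "m", "C10H16N5O13P3", -4), c("adp_m", "m", "C10H15N5O10P2", -3),
    c("pi_e", "e", "H3O4P", 0), c("pi_c", "c", "H3O4P", 0),
    c("pi_m", "m", "H3O4P", 0),
    c("h2o_e", "e", "H2O", 0), c("h2o_c", "c", "H2O", 0),
    c("h2o_m", "m", "H2O", 0),
    c("co2_e", "e", "CO2", 0), c("co2_c", "c", "CO2", 0),
    c("co2_m", "m", "CO2", 0),
    c("o2_e", "e", "O2", 0), c("o2_c", "c", "O2", 0), c("o2_m", "m", "O2", 0),
    c("o2s_c", "c", "O2", -1), c("o2s_m", "m", "O2", -1),
    c("h2o2_c", "c", "H2O2", 0), c("h2o2_m", "m", "H2O2", 0),
    c("nh4_m", "m", "H4N", 1), c("nh4_c", "c", "H4N", 1),
    c("nh4_e", "e", "H4N", 1),
    c("gsh_c", "c", "C12H27N3O9", 0), c("gsh_e", "e", "C12H27N3O9", 0),
    c("gssg_c", "c", "C24H52N6O18", 0),
    c("gssg_e", "e", "C24H52N6O18", 0),
    c("ascb_e", "e", "C6H8O6", 0), c("ascb_c", "c", "C6H8O6", 0),
    c("dhascb_c", "c", "C6H6O6", 0), c("dhascb_e", "e", "C6H6O6", 0),
    c("heme_e", "e", "C34H32FeN4O4", 0), c("heme_c", "c", "C34H32FeN4O4", 0),
    c("bv_c", "c", "C33H34N4O6", 0), c("bv_e", "e", "C33H34N4O6", 0),
    c("co_c", "c", "CO", 0), c("co_e", "e", "CO", 0),
    c("fe2_c", "c", "Fe", 2), c("fe2_e", "e", "Fe", 2),
    c("biom_c", "c", "C18.9H41.9N4O13.4P0.1", 0),
    c("biom_e", "e", "C18.9H41.9N4O13.4P0.1", 0)
  )
  data.frame(id = m[, 1], name = m[, 1], compartment = m[, 2],
             formula = m[, 3], charge = as.integer(m[, 4]),
             stringsAsFactors = FALSE)
}

.toyReactions <- function() {
  R <- function(id, stoich, lb = 0, ub = 1000, gpr = "", subsystem = "")
    list(id = id, stoichiometry = stoich, lower_bound = lb, upper_bound = ub,
         gpr = gpr, subsystem = subsystem)
  ex <- function(met) {
    R(paste0("EX_", sub("_e$", "", met)), stats::setNames(-1, met),
      lb = -1000, ub = 1000, subsystem = "exchange")
  }
  c(
    lapply(c("glc_e", "gln_e", "aa_e", "fa_e", "o2_e", "rib_e", "heme_e",
             "ascb_e", "pi_e", "h2o_e", "co2_e", "lac_e", "nh4_e", "co_e",
             "bv_e", "fe2_e", "dhascb_e", "gssg_e", "gsh_e", "biom_e"), ex),
    list(
      R("GLCt", c(glc_e = -1, glc_c = 1), gpr = "SLC2A1",
        subsystem = "transport"),
      R("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
        gpr = "HK1", subsystem = "glycolysis"),
      R("HEX2", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
        gpr = "GCK", subsystem = "glycolysis"),
      R("PYK", c(g6p_c = -1, nad_c = -2, adp_c = -3, pi_c = -2,
                 pyr_c = 2, nadh_c = 2, atp_c = 3, h2o_c = 2),
        gpr = "PKM", subsystem = "glycolysis"),
      R("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1),
        lb = -1000, gpr = "LDHA", subsystem = "lactate"),
      R("LACt", c(lac_c = -1, lac_e = 1), gpr = "SLC16A1",
        subsystem = "lactate"),
      R("G6PD", c(g6p_c = -1, nadp_c = -2, h2o_c = -1,
                  ru5p_c = 1, co2_c = 1, nadph_c = 2),
        gpr = "G6PD and PGD", subsystem = "ppp"),
      R("RPI", c(ru5p_c = -1, r5p_c = 1), lb = -1000, gpr = "RPIA",
        subsystem = "ppp"),
      R("TKT", c(ru5p_c = -6, h2o_c = -1, g6p_c = 5, pi_c = 1),
        gpr = "TKT", subsystem = "ppp"),
      R("RIBt", c(rib_e = -1, rib_c = 1), gpr = "SLC2A2",
        subsystem = "nucleotide_salvage"),
      R("RBK", c(rib_c = -1, atp_c = -1, r5p_c = 1, adp_c = 1),
        gpr = "RBKS", subsystem = "nucleotide_salvage"),
      R("PYRtm", c(pyr_c = -1, pyr_m = 1), gpr = "MPC1",
        subsystem = "pyruvate_oxidation"),
      R("PDH", c(pyr_m = -1, nad_m = -1, h2o_m = -1,
                 ac_m = 1, co2_m = 1, nadh_m = 1),
        gpr = "PDHA1", subsystem = "pyruvate_oxidation"),
      R("TCA", c(ac_m = -1, h2o_m = -2, nad_m = -4, co2_m = 2, nadh_m = 4),
        gpr = "CS", subsystem = "tca"),
      R("ETC", c(nadh_m = -1, o2_m = -0.5, adp_m = -2.5, pi_m = -2.5,
                 nad_m = 1, atp_m = 2.5, h2o_m = 3.5),
        gpr = "NDUFS1", subsystem = "oxphos"),
      R("NADHT", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
        lb = -1000, gpr = "MDH1", subsystem = "oxphos"),
      R("ATPt", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
        lb = -1000, gpr = "SLC25A4", subsystem = "oxphos"),
      R("PItm", c(pi_c = -1, pi_m = 1), lb = -1000, gpr = "SLC25A3",
        subsystem = "oxphos"),
      R("O2t", c(o2_e = -1, o2_c = 1), subsystem = "transport"),
      R("O2tm", c(o2_c = -1, o2_m = 1), subsystem = "transport"),
      R("CO2tm", c(co2_m = -1, co2_c = 1), lb = -1000,
        subsystem = "transport"),
      R("CO2t", c(co2_c = -1, co2_e = 1), lb = -1000, subsystem = "transport"),
      R("H2Ot", c(h2o_e = -1, h2o_c = 1), lb = -1000, subsystem = "transport"),
      R("H2Otm", c(h2o_c = -1, h2o_m = 1), lb = -1000,
        subsystem = "transport"),
      R("PIt", c(pi_e = -1, pi_c = 1), lb = -1000, subsystem = "transport"),
      R("GLNt", c(gln_e = -1, gln_c = 1), gpr = "SLC1A5",
        subsystem = "glutaminolysis"),
      R("GLNtm", c(gln_c = -1, gln_m = 1), gpr = "SLC25A22",
        subsystem = "glutaminolysis"),
      R("GLS", c(gln_m = -1, h2o_m = -1, glu_m = 1, nh4_m = 1),
        gpr = "GLS", subsystem = "glutaminolysis"),
      R("GLUD", c(glu_m = -1, nad_m = -1, h2o_m = -1,
                  akg_m = 1, nh4_m = 1, nadh_m = 1),
        gpr = "GLUD1", subsystem = "glutaminolysis"),
      R("AKGOX", c(akg_m = -1, h2o_m = -3, nad_m = -3,
                   co2_m = 3, ac_m = 1, nadh_m = 3),
        gpr = "OGDH", subsystem = "glutaminolysis"),
      R("GLUtm", c(glu_m = -1, glu_c = 1), lb = -1000, gpr = "SLC25A18",
        subsystem = "glutaminolysis"),
      R("AASYN", c(glu_c = -1, h2o_c = -1, aa_c = 1, co2_c = 1),
        gpr = "GOT1", subsystem = "aa_synthesis"),
      R("AAt", c(aa_e = -1, aa_c = 1), gpr = "SLC7A5",
        subsystem = "aa_transport"),
      R("PROTS", c(aa_c = -1, atp_c = -1, h2o_c = -1,
                   aax_c = 1, adp_c = 1, pi_c = 1),
        gpr = "EEF2", subsystem = "biosynthesis"),
      R("FAt", c(fa_e = -1, fa_c = 1), gpr = "CD36", subsystem = "lipid"),
      R("CPT1", c(fa_c = -1, atp_c = -1, h2o_c = -1,
                  fa_m = 1, adp_c = 1, pi_c = 1),
        gpr = "CPT1A", subsystem = "fao"),
      R("FAOX", c(fa_m = -1, h2o_m = -6, nad_m = -6, ac_m = 4, nadh_m = 6),
        gpr = "ACADVL", subsystem = "fao"),
      R("LIPS2", c(fa_c = -1, lip_c = 1), gpr = "ACSL1", subsystem = "lipid"),
      R("LIPS1", c(ac_c = -4, nadph_c = -6, atp_c = -1,
                   lip_c = 1, nadp_c = 6, adp_c = 1, pi_c = 1, h2o_c = 5),
        gpr = "FASN", subsystem = "lipid_synthesis"),
      R("ACt", c(ac_m = -1, ac_c = 1), gpr = "SLC25A1",
        subsystem = "lipid_synthesis"),
      R("GSS", c(aa_c = -3, atp_c = -1, h2o_c = -1,
                 gsh_c = 1, adp_c = 1, pi_c = 1),
        gpr = "GSS", subsystem = "glutathione"),
      R("GPX", c(h2o2_c = -1, gsh_c = -2, gssg_c = 1, h2o_c = 2),
        gpr = "GPX1", subsystem = "glutathione"),
      R("GSR", c(gssg_c = -1, nadph_c = -1, gsh_c = 2, nadp_c = 1),
        gpr = "GSR", subsystem = "glutathione"),
      R("GSHSOX", c(gsh_c = -2, o2s_c = -2, gssg_c = 1, h2o2_c = 1, o2_c = 1),
        gpr = "GSTO1", subsystem = "glutathione_detox"),
      R("GSSGt", c(gssg_c = -1, gssg_e = 1), gpr = "ABCC1",
        subsystem = "glutathione"),
      R("GSHt", c(gsh_c = -1, gsh_e = 1), gpr = "SLC7A11",
        subsystem = "glutathione"),
      R("SODm", c(o2s_m = -2, o2_m = 1, h2o2_m = 1), gpr = "SOD2",
        subsystem = "sod"),
      R("SODc", c(o2s_c = -2, o2_c = 1, h2o2_c = 1), gpr = "SOD1",
        subsystem = "sod"),
      R("O2St", c(o2s_m = -1, o2s_c = 1), lb = -1000,
        subsystem = "transport"),
      R("H2O2tm", c(h2o2_m = -1, h2o2_c = 1), subsystem = "transport"),
      R("CAT", c(h2o2_c = -2, h2o_c = 2, o2_c = 1), gpr = "CAT",
        subsystem = "antioxidant"),
      R("ASCBt", c(ascb_e = -1, ascb_c = 1), gpr = "SLC23A1",
        subsystem = "ascorbate"),
      R("ASCBSOX", c(ascb_c = -1, o2s_c = -2,
                     dhascb_c = 1, h2o2_c = 1, o2_c = 1),
        subsystem = "ascorbate_detox"),
      R("GRX", c(dhascb_c = -1, nadph_c = -1, ascb_c = 1, nadp_c = 1),
        gpr = "GLRX", subsystem = "ascorbate"),
      R("DHAt", c(dhascb_c = -1, dhascb_e = 1), subsystem = "transport"),
      R("NOX", c(nadph_c = -1, o2_c = -2, nadp_c = 1, o2s_c = 2),
        gpr = "CYBB", subsystem = "nox"),
      R("HEMEt", c(heme_e = -1, heme_c = 1), gpr = "SLC48A1",
        subsystem = "heme"),
      R("HMOX", c(heme_c = -1, o2_c = -3, nadph_c = -3,
                  bv_c = 1, co_c = 1, fe2_c = 1, nadp_c = 3, h2o_c = 3),
        gpr = "HMOX1", subsystem = "heme"),
      R("COt", c(co_c = -1, co_e = 1), subsystem = "transport"),
      R("BVt", c(bv_c = -1, bv_e = 1), subsystem = "transport"),
      R("FE2t", c(fe2_c = -1, fe2_e = 1), subsystem = "transport"),
      R("NH4tm", c(nh4_m = -1, nh4_c = 1), subsystem = "transport"),
      R("NH4t", c(nh4_c = -1, nh4_e = 1), subsystem = "transport"),
      R("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
        subsystem = "demand"),
      R("BIOMASS", c(aax_c = -4, r5p_c = -0.1, lip_c = -0.3,
                     atp_c = -8, h2o_c = -8,
                     biom_c = 1, adp_c = 8, pi_c = 8),
        subsystem = "biomass"),
      R("BIOMt", c(biom_c = -1, biom_e = 1), subsystem = "transport")
    )
  )
}

#' Build the toy T cell metabolic network
#'
#' A fixed, hand-authored three-compartment model of central T cell
#' metabolism (see the package vignette for the design rationale). The model
#' is flux-consistent with open exchange bounds, carbon/oxygen balanced in
#' every internal reaction, and its biomass reaction is the objective.
#'
#' @return A \linkS4class{MetabolicModel}.
#' @export
buildToyNetwork <- function() {
  MetabolicModel(.toyMetabolites(), .toyReactions(), objective = "BIOMASS")
}

#' Default simulated T cell uptake medium
#'
#' Maximal uptake rates (mmol/gDW/h) for the toy network: glucose,
#' glutamine, an amino-acid pool, a fatty acid, oxygen, ribose, heme,
#' ascorbate, phosphate and water. An explicit, configurable stand-in for a
#' physiological T cell medium.
#'
#' @return Named numeric vector usable with \code{\link{applyMedium}}.
#' @export
defaultMedium <- function() {
  c(EX_glc = 10, EX_gln = 5, EX_aa = 4, EX_fa = 2, EX_o2 = 20,
    EX_rib = 1, EX_heme = 0.2, EX_ascb = 0.5, EX_pi = 1000, EX_h2o = 1000)
}

#' Mandatory core reactions for context-specific extraction
#'
#' Reactions every T cell context model must retain regardless of
#' expression: biomass production and export, the ATP maintenance demand,
#' the mitochondrial respiratory chain (all subsets keep functional
#' mitochondria), and the non-enzymatic membrane passages of oxygen and
#' superoxide. Keeping the gas-diffusion steps mandatory ensures the
#' respiratory chain is fed by imported oxygen rather than by a
#' detoxification side loop that expression may silence.
#'
#' @param epsilon minimum activation flux for the core.
#' @return A \linkS4class{CoreSet}.
#' @export
mandatoryCore <- function(epsilon = 1e-4) {
  CoreSet(c("BIOMASS", "BIOMt", "EX_biom", "ATPM", "ETC",
            "O2t", "O2tm", "O2St"),
          epsilon = epsilon)
}

#' Archetype pathway multipliers
#'
#' Per-gene expression multipliers defining the three cell-type archetypes:
#' \code{alps_like} (activated, glycolysis/glutaminolysis/heme-oxygenase
#' high; PPP, FAO, amino-acid import and ascorbate recovery low),
#' \code{ebv_like} (activated and metabolically flexible: glycolysis with
#' redundant hexokinases, ribose salvage and glutathione synthesis high) and
#' \code{hd_like} (resting oxidative: FAO, OXPHOS, PPP and antioxidant
#' capacity high, glycolysis and biosynthesis low). Stored as data so the
#' archetypes are tunable without touching code.
#'
#' @return data.frame with columns \code{gene}, \code{alps_like},
#'   \code{ebv_like}, \code{hd_like}.
#' @export
archetypeMultipliers <- function() {
  path <- system.file("extdata", "archetype_multipliers.tsv",
                      package = "TcellFlux")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Archetype specification
#'
#' @param label one of \code{"alps_like"}, \code{"ebv_like"},
#'   \code{"hd_like"}.
#' @param multipliers named per-gene multipliers; defaults to the shipped
#'   table column for \code{label}.
#' @param baseline baseline expression level, default 10.
#' @param noiseCv lognormal coefficient of variation of replicate noise,
#'   default 0.1.
#' @param seed RNG seed for replicate simulation.
#' @return An object of class \code{ArchetypeSpec} (a list).
#' @export
archetypeSpec <- function(label = c("alps_like", "ebv_like", "hd_like"),
                          multipliers = NULL, baseline = 10,
                          noiseCv = 0.1, seed = 1L) {
  label <- match.arg(label)
  if (is.null(multipliers)) {
    tab <- archetypeMultipliers()
    multipliers <- stats::setNames(tab[[label]], tab$gene)
  }
  ## multiplier 0 marks a gene the cell type does not express: it is omitted
  ## from the simulated profiles entirely (not detected), which downstream
  ## scores as 0 and closes the reaction's eFlux bounds
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  multipliers <- multipliers[multipliers > 0]
  if (length(multipliers) == 0) stop("no expressed genes in archetype")
  stopifnot(noiseCv >= 0, baseline > 0)
  structure(list(label = label, multipliers = multipliers,
                 baseline = baseline, noiseCv = noiseCv,
                 seed = as.integer(seed)),
            class = "ArchetypeSpec")
}

#' Simulate replicate expression profiles for an archetype
#'
#' Per-gene expression is baseline x archetype multiplier x multiplicative
#' lognormal noise with the requested coefficient of variation (unit mean),
#' deterministic for a given seed.
#'
#' @param spec an \code{ArchetypeSpec} from \code{\link{archetypeSpec}}.
#' @param nReplicates number of replicates, default 3.
#' @return List of \linkS4class{ExpressionProfile}s.
#' @export
simulateExpression <- function(spec, nReplicates = 3L) {
  stopifnot(inherits(spec, "ArchetypeSpec"))
  mu <- spec$baseline * spec$multipliers
  sdlog <- sqrt(log(1 + spec$noiseCv^2))
  set.seed(spec$seed)
  lapply(seq_len(nReplicates), function(k) {
    noise <- stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    ExpressionProfile(stats::setNames(mu * noise, names(mu)),
                      label = spec$label, nReplicates = 1L)
  })
}

#' Default in silico inhibitor panel
#'
#' The inhibitors simulated in the comparative analysis: hexokinase (HK1),
#' CPT1-gated fatty-acid oxidation, G6PD (oxidative PPP), glutamine uptake,
#' and the mitochondrial glutaminase. Enzyme inhibitors are mapped to
#' reactions through GPR gene membership; glutamine uptake is blocked at its
#' exchange reaction.
#'
#' @return Named list of \linkS4class{PerturbationSpec}s.
#' @export
defaultInhibitorPanel <- function() {
  list(
    hexokinase = PerturbationSpec("hexokinase", genes = "HK1"),
    CPT1 = PerturbationSpec("CPT1", genes = "CPT1A"),
    G6PD = PerturbationSpec("G6PD", genes = "G6PD"),
    glutamine_uptake = PerturbationSpec("glutamine_uptake",
                                        reactions = "EX_gln"),
    mito_glutaminase = PerturbationSpec("mito_glutaminase", genes = "GLS")
  )
}
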