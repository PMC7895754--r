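#' Build the curated reduced seven-pathway macrophage network
#'
#' Constructs the shipped reference model of macrophage M1-M2 polarization:
#' six receptor-mediated cytokine pathways (IFN-gamma, TNF-alpha, IL-1beta,
#' IL-4, IL-10, VEGF) plus an oxygen-sensing (PHD/HIF) pathway, with
#' receptor trafficking (binding, activation, internalization, recycling,
#' degradation), canonical signal transduction (JAK/STAT1/IRF1, RIP1 and
#' IRAK/TRAF6 to IKK/IkB/NF-kB, MAPKs/AP-1/CREB/C/EBPbeta, PI3K/AKT,
#' STAT3, STAT6/IRF4), negative feedback (SOCS1, SOCS3, A20), microRNA
#' regulation (miR-155, miR-93, miR-146b), mutually antagonistic HIF1a/HIF2a
#' control, and a transcription/translation/secretion marker cassette for
#' the M1 panel (iNOS, TNF-alpha, IL-1beta, IL-12, CXCL9, CXCL10,
#' IFN-gamma, itaconate) and M2 panel (ARG1, IL-10, IL-1Ra, VEGF165a).
#' Secreted cytokines feed back onto their own receptors through the shared
#' extracellular pool (autocrine closure).
#'
#' The parameterization is desk-calibrated: rate constants are chosen to
#' reproduce the qualitative directional responses and plausible timescales
#' (receptor events minutes, transcription factors 0.5-4 h, markers
#' 4-48 h); it does not claim numerical identity with any published
#' parameter set. Six intervention-relevant parameters carry their
#' conventional names: `kf3` (STAT1 activation), `k26` (STAT6
#' dephosphorylation), `k127` (STAT3 dephosphorylation), `k85` (IRF1
#' degradation), `k101` (SOCS1 degradation), `kf62` (PHD-mediated HIF1a
#' hydroxylation; with `kf63` for HIF2a these are the oxygen-scaled
#' parameters).
#'
#' @param config Optional named numeric vector of parameter overrides
#'   applied after construction.
#' @return An `mp_network` annotated with `marker_panel`,
#'   `oxygen_parameters`, `molecular_weights`, `medium_volume_ml` and
#'   `pathway_modules`.
#' @export
build_reference_network <- function(config = NULL) {
  SP <- list(); RX <- list(); PM <- list(); MO <- list()
  pdef <- function(id, value, desc = "") {
    if (!is.null(PM[[id]])) {
      if (PM[[id]]$value != value)
        stop("parameter '", id, "' redefined with a different value")
      return(id)
    }
    PM[[id]] <<- parameter(id, value, desc)
    id
  }
  sdef <- function(id, ...) { if (is.null(SP[[id]])) SP[[id]] <<- species(id, ...); id }
  rdef <- function(id, reactants = NULL, products = NULL, law, module,
                   tags = character()) {
    RX[[id]] <<- reaction(id, reactants, products, law,
                          tags = c(tags, paste0("module:", module)))
    id
  }
  # catalytic conversion  X (+ cat) -> Y (+ cat), mass action
  cat_rx <- function(id, from, to, catalyst, k, module, tags = character()) {
    kid <- pdef(paste0("k_", id), k)
    if (is.null(catalyst)) {
      rdef(id, reactants = stats::setNames(1, from),
           products = stats::setNames(1, to),
           law = rate_law("mass_action", kid), module = module, tags = tags)
    } else {
      rdef(id, reactants = stats::setNames(c(1, 1), c(from, catalyst)),
           products = stats::setNames(c(1, 1), c(to, catalyst)),
           law = rate_law("mass_action", kid), module = module, tags = tags)
    }
  }
  # degradation catalysed by an enzyme/regulator (substrate consumed)
  cat_deg <- function(id, substrate, catalyst, k, module) {
    kid <- pdef(paste0("k_", id), k)
    rdef(id, reactants = stats::setNames(c(1, 1), c(substrate, catalyst)),
         products = stats::setNames(1, catalyst),
         law = rate_law("mass_action", kid), module = module)
  }
  decay <- function(species_id, k, module, pid = NULL, tags = character()) {
    kid <- if (is.null(pid)) pdef(paste0("kd_", species_id), k) else pdef(pid, k)
    rdef(paste0("r_", species_id, "_decay"),
         reactants = stats::setNames(1, species_id),
         law = rate_law("first_order_decay", kid), module = module,
         tags = tags)
  }
  # transcription-style synthesis with additive regulator channels
  synth_channels <- function(target, channels, module, tags = "transcription") {
    for (i in seq_along(channels)) {
      ch <- channels[[i]]
      rid <- paste0("r_", target, "_syn", i)
      kid <- pdef(paste0("k_", target, "_syn", i), ch$k)
      law <- switch(ch$type,
        basal = rate_law("synthesis", kid),
        act = rate_law("hill_activation", kid, K = ch$K,
                       n = if (is.null(ch$n)) 2 else ch$n, regulator = ch$reg),
        inh = rate_law("hill_inhibition", kid, K = ch$K,
                       n = if (is.null(ch$n)) 2 else ch$n, regulator = ch$reg))
      rdef(rid, products = stats::setNames(1, target), law = law,
           module = module, tags = tags)
    }
  }
  basal <- function(k) list(type = "basal", k = k)
  act <- function(reg, k, K, n = 2) list(type = "act", reg = reg, k = k, K = K, n = n)
  inh <- function(reg, k, K, n = 2) list(type = "inh", reg = reg, k = k, K = K, n = n)

  # --- receptor trafficking -------------------------------------------------
  # closed cycle: surface receptor R, signalling complex C, internalized Ri;
  # ligand is consumed by binding and destroyed upon internalization.
  receptor_module <- function(tag, lig, R0, module, kf = 1e-5, kr = 0.2,
                              kint = 1, krec = 0.5, closed = TRUE) {
    R <- sdef(paste0("R_", tag), role = "receptor", initial_amount = R0)
    C <- sdef(paste0("C_", tag), role = "complex", initial_amount = 0)
    Ri <- sdef(paste0("Ri_", tag), role = "receptor", initial_amount = 0,
               compartment = "cytoplasm")
    rdef(paste0("r_", tag, "_bind"),
         reactants = stats::setNames(c(1, 1), c(lig, R)),
         products = stats::setNames(1, C),
         law = rate_law("mass_action", pdef(paste0("kf_", tag, "_bind"), kf)),
         module = module)
    rdef(paste0("r_", tag, "_unbind"),
         reactants = stats::setNames(1, C),
         products = stats::setNames(c(1, 1), c(lig, R)),
         law = rate_law("first_order_decay", pdef(paste0("kr_", tag), kr)),
         module = module)
    cat_rx(paste0("r_", tag, "_internalize"), C, Ri, NULL, kint, module)
    cat_rx(paste0("r_", tag, "_recycle"), Ri, R, NULL, krec, module)
    if (closed)
      MO[[length(MO) + 1]] <<- moiety(paste0(tag, "_total"),
                                      stats::setNames(c(1, 1, 1), c(R, C, Ri)))
    C
  }
  ligand <- function(id, mw, module, kdeg = 0.05) {
    sdef(id, role = "ligand", compartment = "extracellular",
         initial_amount = 0)
    decay(id, kdeg, module)
    id
  }
  # activation/deactivation cycle; returns active form id
  cycle <- function(base, pool, deact_k, module, deact_pid = NULL,
                    basal_act = NULL) {
    X <- sdef(base, role = "protein", initial_amount = pool)
    Xp <- sdef(paste0(base, "p"), role = "phospho-protein", initial_amount = 0)
    kid <- if (is.null(deact_pid)) pdef(paste0("k_", Xp, "_deact"), deact_k)
           else pdef(deact_pid, deact_k)
    rdef(paste0("r_", Xp, "_deact"), reactants = stats::setNames(1, Xp),
         products = stats::setNames(1, X),
         law = rate_law("first_order_decay", kid), module = module)
    if (!is.null(basal_act))
      cat_rx(paste0("r_", base, "_act_basal"), X, Xp, NULL, basal_act, module)
    Xp
  }
  activate_by <- function(base, catalyst, k, module, pid = NULL) {
    kid <- if (is.null(pid)) pdef(paste0("k_", base, "_act_", catalyst), k)
           else pdef(pid, k)
    rdef(paste0("r_", base, "_act_", catalyst),
         reactants = stats::setNames(c(1, 1), c(base, catalyst)),
         products = stats::setNames(c(1, 1), c(paste0(base, "p"), catalyst)),
         law = rate_law("mass_action", kid), module = module)
  }
  deact_by <- function(base, catalyst, k, module) {
    Xp <- paste0(base, "p")
    cat_rx(paste0("r_", Xp, "_deact_", catalyst), Xp, base, catalyst, k, module)
  }

  # ligands (shared extracellular pool; autocrine closure via secretion)
  L_IFNG <- ligand("L_IFNG", 34000, "IFNG")
  L_TNFA <- ligand("L_TNFA", 17000, "TNFA")
  L_IL1B <- ligand("L_IL1B", 17000, "IL1B")
  L_IL4  <- ligand("L_IL4", 15000, "IL4")
  L_IL10 <- ligand("L_IL10", 18000, "IL10")
  L_VEGFA <- ligand("L_VEGFA", 38000, "VEGF")
  L_VEGFB <- ligand("L_VEGFB", 38000, "VEGF")

  C_IFNG <- receptor_module("IFNGR", L_IFNG, 2e4, "IFNG")
  C_TNFR <- receptor_module("TNFR", L_TNFA, 2e4, "TNFA")
  C_IL1R <- receptor_module("IL1R", L_IL1B, 2e4, "IL1B")
  C_IL10R <- receptor_module("IL10R", L_IL10, 2e4, "IL10")
  # IL-4 receptor: open cycle (synthesis upregulated by IL-10/STAT3)
  C_IL4R <- receptor_module("IL4R", L_IL4, 1e4, "IL4", closed = FALSE)
  synth_channels("R_IL4R", list(basal(500), act("STAT3p", 1000, K = 1e4)),
                 "IL4", tags = "translation")
  decay("R_IL4R", 0.05, "IL4")
  decay("Ri_IL4R", 0.05, "IL4")
  # VEGFR1 binds both isoforms; only the 165a complex signals
  C_VEGFR <- receptor_module("VEGFR", L_VEGFA, 2e4, "VEGF")
  # 165b competes for the same surface receptor (non-signalling complex)
  sdef("Cb_VEGFR", role = "complex", initial_amount = 0)
  rdef("r_VEGFR_bind_b",
       reactants = c(L_VEGFB = 1, R_VEGFR = 1), products = c(Cb_VEGFR = 1),
       law = rate_law("mass_action", pdef("kf_VEGFR_bind_b", 1e-5)),
       module = "VEGF")
  rdef("r_VEGFR_unbind_b", reactants = c(Cb_VEGFR = 1),
       products = c(L_VEGFB = 1, R_VEGFR = 1),
       law = rate_law("first_order_decay", pdef("kr_VEGFR_b", 0.2)),
       module = "VEGF")
  cat_rx("r_VEGFR_internalize_b", "Cb_VEGFR", "Ri_VEGFR", NULL, 1, "VEGF")
  MO[[length(MO)]] <- moiety("VEGFR_total",
                             c(R_VEGFR = 1, C_VEGFR = 1, Ri_VEGFR = 1,
                               Cb_VEGFR = 1))

  # --- oxygen sensing -------------------------------------------------------
  sdef("PHD", role = "protein", initial_amount = 1e4, is_constant = TRUE)
  sdef("HIF1a", role = "protein", initial_amount = 0)
  sdef("HIF2a", role = "protein", initial_amount = 0)
  synth_channels("HIF1a", list(inh("STAT6p", 3000, K = 2e4),
                               act("STAT1p", 1500, K = 2e4)),
                 "HYPOXIA", tags = "translation")
  synth_channels("HIF2a", list(inh("STAT1p", 2000, K = 2e4),
                               act("STAT6p", 1000, K = 2e4)),
                 "HYPOXIA", tags = "translation")
  pdef("kf62", 1e-4, "PHD-mediated HIF1a hydroxylation (oxygen-scaled)")
  pdef("kf63", 1e-4, "PHD-mediated HIF2a hydroxylation (oxygen-scaled)")
  rdef("r_HIF1a_hydroxylation", reactants = c(HIF1a = 1, PHD = 1),
       products = c(PHD = 1), law = rate_law("mass_action", "kf62"),
       module = "HYPOXIA")
  rdef("r_HIF2a_hydroxylation", reactants = c(HIF2a = 1, PHD = 1),
       products = c(PHD = 1), law = rate_law("mass_action", "kf63"),
       module = "HYPOXIA")
  decay("HIF1a", 0.05, "HYPOXIA")
  decay("HIF2a", 0.05, "HYPOXIA")

  # --- IFNG: JAK/STAT1/IRF1, STAT3 antagonism, NF-kB cross-talk ------------
  JAK1p <- cycle("JAK1", 2e4, 2, "IFNG")
  activate_by("JAK1", C_IFNG, 5e-4, "IFNG")
  deact_by("JAK1", "SOCS1", 2e-4, "IFNG")
  deact_by("JAK1", "SOCS3", 1e-4, "IFNG")
  STAT1p <- cycle("STAT1", 0, 2, "IFNG")   # pool filled by synthesis below
  activate_by("STAT1", JAK1p, 5e-4, "IFNG", pid = "kf3")
  deact_by("STAT1", "STAT3p", 1e-5, "IFNG")
  synth_channels("STAT1", list(inh("miR146b", 1e4, K = 1500)),
                 "IFNG", tags = "translation")
  decay("STAT1", 0.1, "IFNG")
  decay("STAT1p", 0.1, "IFNG")

  # --- TNFA: RIP1 axis ------------------------------------------------------
  RIP1a <- cycle("RIP1", 1e5, 2, "TNFA")
  activate_by("RIP1", C_TNFR, 2e-4, "TNFA")

  # --- IL1B: IRAK4/TRAF6 axis (IRAK4 expression is a miR-93 target) --------
  sdef("IRAK4", role = "protein", initial_amount = 5000)
  sdef("IRAK4a", role = "phospho-protein", initial_amount = 0)
  synth_channels("IRAK4", list(inh("miR93", 1000, K = 800)),
                 "IL1B", tags = "translation")
  decay("IRAK4", 0.1, "IL1B")
  rdef("r_IRAK4_act", reactants = c(IRAK4 = 1, C_IL1R = 1),
       products = c(IRAK4a = 1, C_IL1R = 1),
       law = rate_law("mass_action", pdef("k_IRAK4_act", 2e-4)),
       module = "IL1B")
  cat_rx("r_IRAK4a_deact", "IRAK4a", "IRAK4", NULL, 2, "IL1B")
  decay("IRAK4a", 0.1, "IL1B")
  TRAF6a <- cycle("TRAF6", 1e5, 2, "IL1B")
  activate_by("TRAF6", "IRAK4a", 2e-4, "IL1B")

  # --- IKK / IkB / NF-kB ----------------------------------------------------
  sdef("IKKb", role = "protein", initial_amount = 0)
  sdef("IKKa", role = "phospho-protein", initial_amount = 0)
  synth_channels("IKKb", list(basal(1000), act("HIF1a", 2000, K = 1.5e4)),
                 "HYPOXIA", tags = "translation")
  decay("IKKb", 0.1, "TNFA")
  cat_rx("r_IKK_act_basal", "IKKb", "IKKa", NULL, 0.005, "TNFA")
  cat_rx("r_IKK_act_TRAF6", "IKKb", "IKKa", "TRAF6p", 2e-5, "IL1B")
  cat_rx("r_IKK_act_RIP1", "IKKb", "IKKa", "RIP1p", 2e-5, "TNFA")
  cat_rx("r_IKK_act_JAK1", "IKKb", "IKKa", "JAK1p", 5e-6, "IFNG")
  cat_rx("r_IKKa_deact", "IKKa", "IKKb", NULL, 2, "TNFA")
  cat_rx("r_IKKa_deact_A20", "IKKa", "IKKb", "A20", 2e-4, "TNFA")
  decay("IKKa", 0.1, "TNFA")

  sdef("NFkB_c", role = "protein", initial_amount = 0)
  sdef("NFkB_n", role = "protein", compartment = "nucleus", initial_amount = 0)
  sdef("NFkB_IkB", role = "complex", initial_amount = 1e5)
  sdef("IkB", role = "protein", initial_amount = 1e4)
  synth_channels("IkB", list(basal(2000), act("NFkB_n", 4e4, K = 2e4)),
                 "TNFA", tags = "translation")
  decay("IkB", 0.25, "TNFA")
  cat_deg("r_IkB_deg_IKK", "IkB", "IKKa", 1e-4, "TNFA")
  rdef("r_NFkB_IkB_release",
       reactants = c(NFkB_IkB = 1, IKKa = 1),
       products = c(NFkB_c = 1, IKKa = 1),
       law = rate_law("mass_action", pdef("k_NFkB_release", 1e-4)),
       module = "TNFA")
  rdef("r_NFkB_bind_IkB", reactants = c(NFkB_c = 1, IkB = 1),
       products = c(NFkB_IkB = 1),
       law = rate_law("mass_action", pdef("k_NFkB_bind", 1e-4)),
       module = "TNFA")
  cat_rx("r_NFkB_import", "NFkB_c", "NFkB_n", NULL, 5, "TNFA")
  rdef("r_NFkB_export", reactants = c(NFkB_n = 1, IkB = 1),
       products = c(NFkB_IkB = 1),
       law = rate_law("mass_action", pdef("k_NFkB_export", 5e-5)),
       module = "TNFA")
  MO[[length(MO) + 1]] <- moiety("NFkB_total",
                                 c(NFkB_c = 1, NFkB_n = 1, NFkB_IkB = 1))

  # --- MAPK cascades, AP-1, CREB, C/EBPbeta --------------------------------
  for (m in c("p38", "ERK", "JNK")) {
    cycle(m, 1e5, 2, "TNFA")
    activate_by(m, "TRAF6p", 5e-5, "IL1B")
    activate_by(m, "RIP1p", 5e-5, "TNFA")
  }
  activate_by("ERK", C_IL4R, 1e-4, "IL4")
  activate_by("ERK", C_IL10R, 1e-4, "IL10")
  activate_by("ERK", C_VEGFR, 1e-4, "VEGF")
  AP1a <- cycle("AP1", 1e4, 1, "TNFA")
  activate_by("AP1", "JNKp", 5e-5, "TNFA")
  CREBa <- cycle("CREB", 1e4, 1, "TNFA")
  activate_by("CREB", "p38p", 5e-5, "TNFA")
  sdef("CEBPb", role = "protein", initial_amount = 0)
  synth_channels("CEBPb", list(basal(200), act("STAT6p", 800, K = 1e4),
                               act("CREBp", 400, K = 5e3)),
                 "IL4", tags = "translation")
  decay("CEBPb", 0.1, "IL4")

  # --- PI3K/AKT -------------------------------------------------------------
  AKTp <- cycle("AKT", 1e5, 2, "IL4")
  activate_by("AKT", C_IL1R, 2e-4, "IL1B")
  activate_by("AKT", C_IL4R, 2e-4, "IL4")
  activate_by("AKT", C_IL10R, 2e-4, "IL10")
  activate_by("AKT", C_VEGFR, 2e-4, "VEGF")

  # --- STAT3 (IL-10, VEGF, IFNG-induced; SOCS1-inhibited) ------------------
  STAT3p <- cycle("STAT3", 1e5, 2, "IL10", deact_pid = "k127",
                  basal_act = 0.008)
  activate_by("STAT3", C_IL10R, 1.5e-4, "IL10")
  activate_by("STAT3", C_VEGFR, 1.2e-4, "VEGF")
  activate_by("STAT3", C_IFNG, 1e-5, "IFNG")
  deact_by("STAT3", "SOCS1", 5e-5, "IL10")
  deact_by("STAT3", "SOCS3", 1e-5, "IL10")

  # --- STAT6 / IRF4 (IL-4) --------------------------------------------------
  STAT6p <- cycle("STAT6", 1e5, 2, "IL4", deact_pid = "k26",
                  basal_act = 0.02)
  activate_by("STAT6", C_IL4R, 2.5e-4, "IL4")
  sdef("IRF4", role = "protein", initial_amount = 0)
  synth_channels("IRF4", list(basal(100), act("STAT6p", 1000, K = 1e4)),
                 "IL4", tags = "translation")
  decay("IRF4", 0.1, "IL4")
  for (g in c("EGR2", "PPARG")) {
    sdef(g, role = "protein", initial_amount = 0)
    synth_channels(g, list(basal(100), act("STAT6p", 1000, K = 1e4)),
                   "IL4", tags = "translation")
    decay(g, 0.1, "IL4")
  }

  # --- feedback regulators --------------------------------------------------
  sdef("SOCS1", role = "protein", initial_amount = 0)
  synth_channels("SOCS1",
                 list(inh("miR155", 500, K = 1000),
                      act("STAT1p", 8000, K = 2e4),
                      act("STAT6p", 8000, K = 2e4),
                      act("NFkB_n", 2000, K = 2e4)),
                 "IFNG", tags = "translation")
  decay("SOCS1", 0.25, "IFNG", pid = "k101")
  sdef("SOCS3", role = "protein", initial_amount = 0)
  synth_channels("SOCS3",
                 list(basal(500), act("STAT3p", 4000, K = 1e4),
                      act("NFkB_n", 4000, K = 2e4)),
                 "IL10", tags = "translation")
  decay("SOCS3", 0.25, "IL10")
  sdef("A20", role = "protein", initial_amount = 0)
  synth_channels("A20", list(basal(200), act("NFkB_n", 8000, K = 2e4)),
                 "TNFA", tags = "translation")
  decay("A20", 0.2, "TNFA")

  # --- microRNAs ------------------------------------------------------------
  sdef("miR155", role = "miRNA", initial_amount = 0)
  synth_channels("miR155",
                 list(inh("STAT3p", 50, K = 1e4),
                      act("NFkB_n", 400, K = 2e4)),
                 "IL1B", tags = "transcription")
  decay("miR155", 0.25, "IL1B")
  sdef("miR93", role = "miRNA", initial_amount = 0)
  synth_channels("miR93",
                 list(inh("NFkB_n", 100, K = 2e4),
                      inh("HIF1a", 100, K = 1.5e4)),
                 "HYPOXIA", tags = "transcription")
  decay("miR93", 0.25, "HYPOXIA")
  sdef("miR146b", role = "miRNA", initial_amount = 0)
  synth_channels("miR146b",
                 list(basal(50), act("STAT3p", 300, K = 1e4)),
                 "IL10", tags = "transcription")
  decay("miR146b", 0.25, "IL10")
  sdef("IRF9", role = "protein", initial_amount = 0)
  synth_channels("IRF9", list(inh("miR93", 200, K = 800),
                              act("STAT1p", 200, K = 2e4)),
                 "IFNG", tags = "translation")
  decay("IRF9", 0.1, "IFNG")

  # --- marker cassettes -----------------------------------------------------
  marker <- function(gene, module, mrna_channels, mrna_decay, tl = 5,
                     prot_decay = 0.15, secrete_to = NULL, sec_rate = NULL,
                     prot_role = "protein") {
    m <- sdef(paste0(gene, "_m"), role = "mRNA", initial_amount = 0)
    p <- sdef(gene, role = prot_role, initial_amount = 0,
              secreted = !is.null(secrete_to))
    synth_channels(m, mrna_channels, module, tags = "transcription")
    decay(m, mrna_decay, module)
    # translation: flux proportional to mRNA (catalytic on transcript)
    rdef(paste0("r_", gene, "_translate"),
         reactants = stats::setNames(1, m),
         products = stats::setNames(c(1, 1), c(m, p)),
         law = rate_law("mass_action", pdef(paste0("k_", gene, "_tl"), tl)),
         module = module, tags = "translation")
    decay(p, prot_decay, module)
    if (!is.null(secrete_to)) {
      rdef(paste0("r_", gene, "_secrete"),
           reactants = stats::setNames(1, p),
           products = stats::setNames(1, secrete_to),
           law = rate_law("first_order_decay",
                          pdef(paste0("k_", gene, "_sec"), sec_rate)),
           module = module, tags = "secretion")
    }
    invisible(p)
  }

  marker("iNOS", "IFNG",
         list(inh("STAT6p", 8, K = 1e4), act("IRF1", 300, K = 3e3),
              act("NFkB_n", 100, K = 2e4), act("HIF1a", 100, K = 1.5e4)),
         mrna_decay = 0.25)
  marker("CXCL9", "IFNG",
         list(basal(10), act("STAT1p", 500, K = 2e4)),
         mrna_decay = 0.25, secrete_to = NULL)
  rdef("r_CXCL9_secrete", reactants = c(CXCL9 = 1),
       law = rate_law("first_order_decay", pdef("k_CXCL9_sec", 0.05)),
       module = "IFNG", tags = "secretion")
  marker("CXCL10", "IFNG",
         list(inh("STAT6p", 10, K = 1e4), act("STAT1p", 500, K = 2e4),
              act("NFkB_n", 200, K = 2e4)),
         mrna_decay = 0.35)
  marker("IL12", "IFNG",
         list(inh("STAT3p", 8, K = 1e4), act("IRF1", 200, K = 3e3),
              act("NFkB_n", 150, K = 2e4), act("HIF1a", 50, K = 1.5e4)),
         mrna_decay = 0.25)
  rdef("r_IL12_secrete", reactants = c(IL12 = 1),
       law = rate_law("first_order_decay", pdef("k_IL12_sec", 0.05)),
       module = "IFNG", tags = "secretion")
  marker("TNFA", "TNFA",
         list(inh("STAT6p", 6, K = 1e4), inh("STAT3p", 6, K = 1e4),
              act("NFkB_n", 250, K = 2e4), act("AP1p", 100, K = 5e3),
              act("HIF1a", 50, K = 1.5e4)),
         mrna_decay = 0.4, tl = 10, prot_decay = 0.2,
         secrete_to = "L_TNFA", sec_rate = 0.05)
  marker("IL1B", "IL1B",
         list(basal(1), act("NFkB_n", 400, K = 2e4),
              act("HIF1a", 150, K = 1.5e4)),
         mrna_decay = 0.3, tl = 10, prot_decay = 0.2,
         secrete_to = "L_IL1B", sec_rate = 0.1)
  marker("IFNG", "IFNG",
         list(basal(2), act("IRF9", 100, K = 2500),
              act("HIF1a", 100, K = 1.5e4)),
         mrna_decay = 0.2, tl = 10, prot_decay = 0.2,
         secrete_to = "L_IFNG", sec_rate = 0.02)
  # itaconate: terminal metabolic M1 readout (production flux reported)
  sdef("ITA", role = "compound", initial_amount = 0)
  rdef("r_ITA_syn1", products = c(ITA = 1),
       law = rate_law("synthesis", pdef("k_ITA_syn1", 5)),
       module = "IFNG", tags = "secretion")
  rdef("r_ITA_syn2", products = c(ITA = 1),
       law = rate_law("hill_activation", pdef("k_ITA_syn2", 200),
                      K = 3e3, n = 2, regulator = "IRF1"),
       module = "IFNG", tags = "secretion")
  decay("ITA", 0.3, "IFNG")

  marker("ARG1", "IL4",
         list(basal(10), act("STAT6p", 600, K = 1e4),
              act("STAT3p", 150, K = 1e4), act("HIF2a", 350, K = 1e4)),
         mrna_decay = 0.1, prot_decay = 0.1)
  marker("IL10", "IL10",
         list(basal(2), act("STAT6p", 200, K = 1e4),
              act("STAT3p", 100, K = 1e4), act("HIF2a", 200, K = 1e4),
              act("CREBp", 50, K = 5e3)),
         mrna_decay = 0.15, tl = 10, prot_decay = 0.2,
         secrete_to = "L_IL10", sec_rate = 0.05)
  # IL-1Ra: M2 marker; secreted form antagonizes IL1R (the sixth autocrine
  # closure: a non-signalling receptor complex competing with IL-1beta)
  ligand("L_IL1RA", 17000, "IL1B", kdeg = 0.05)
  marker("IL1RA", "IL4",
         list(basal(10), act("STAT6p", 200, K = 1e4),
              act("STAT3p", 150, K = 1e4), act("NFkB_n", 50, K = 2e4)),
         mrna_decay = 0.1, prot_decay = 0.1,
         secrete_to = "L_IL1RA", sec_rate = 0.05)
  sdef("Cb_IL1R", role = "complex", initial_amount = 0)
  rdef("r_IL1R_bind_ra", reactants = c(L_IL1RA = 1, R_IL1R = 1),
       products = c(Cb_IL1R = 1),
       law = rate_law("mass_action", pdef("kf_IL1R_bind_ra", 1e-5)),
       module = "IL1B")
  rdef("r_IL1R_unbind_ra", reactants = c(Cb_IL1R = 1),
       products = c(L_IL1RA = 1, R_IL1R = 1),
       law = rate_law("first_order_decay", pdef("kr_IL1R_ra", 0.2)),
       module = "IL1B")
  cat_rx("r_IL1R_internalize_ra", "Cb_IL1R", "Ri_IL1R", NULL, 1, "IL1B")
  for (i in seq_along(MO))
    if (MO[[i]]$name == "IL1R_total")
      MO[[i]] <- moiety("IL1R_total",
                        c(R_IL1R = 1, C_IL1R = 1, Ri_IL1R = 1, Cb_IL1R = 1))
  marker("VEGFA", "VEGF",
         list(inh("STAT3p", 10, K = 1e4), inh("miR93", 10, K = 800),
              act("HIF1a", 250, K = 1.5e4), act("STAT1p", 50, K = 2e4),
              act("STAT6p", 50, K = 1e4)),
         mrna_decay = 0.15, tl = 10, prot_decay = 0.2,
         secrete_to = "L_VEGFA", sec_rate = 0.1)
  # IRF1: IFNG-axis master TF (also a hypoxia target; IL-4-repressed)
  sdef("IRF1", role = "protein", initial_amount = 0)
  synth_channels("IRF1",
                 list(inh("STAT6p", 100, K = 1e4),
                      act("STAT1p", 3500, K = 4e4),
                      act("HIF1a", 500, K = 1.5e4)),
                 "IFNG", tags = "translation")
  decay("IRF1", 0.3, "IFNG", pid = "k85")

  net <- network(species = SP, reactions = RX, parameters = PM,
                 moieties = MO, name = "reference_macrophage",
                 annotations = list(
                   oxygen_parameters = c("kf62", "kf63"),
                   molecular_weights = c(L_IFNG = 34000, L_TNFA = 17000,
                                         L_IL1B = 17000, L_IL4 = 15000,
                                         L_IL10 = 18000, L_VEGFA = 38000,
                                         L_VEGFB = 38000),
                   medium_volume_ml = 1e-6,
                   marker_panel = reference_marker_panel()))
  if (!is.null(config) && length(config)) net <- set_parameters(net, config)
  net
}

#' Default M1/M2 marker panel of the reference network
#'
#' M1: iNOS, IL-12, CXCL9 (protein levels), CXCL10 (mRNA), TNF-alpha,
#' IL-1beta, IFN-gamma, itaconate (production rates). M2: ARG1, IL-1Ra
#' (protein levels), IL-10, VEGF165a (production rates).
#'
#' @return An [marker_panel()] object.
#' @export
reference_marker_panel <- function() {
  marker_panel(
    m1 = data.frame(
      species = c("iNOS", "IL12", "CXCL9", "CXCL10_m", "L_TNFA", "L_IL1B",
                  "L_IFNG", "ITA"),
      readout = c("level", "level", "level", "mRNA", "production_rate",
                  "production_rate", "production_rate", "production_rate"),
      stringsAsFactors = FALSE),
    m2 = data.frame(
      species = c("ARG1", "IL1RA", "L_IL10", "L_VEGFA"),
      readout = c("level", "level", "production_rate", "production_rate"),
      stringsAsFactors = FALSE))
}

#' Pathway-module census of a network
#'
#' Reactions are assigned to exactly one of the seven pathway modules via
#' `module:` tags; species are attributed to the module(s) of the reactions
#' that touch them.
#'
#' @param net An `mp_network` with module-tagged reactions.
#' @return Named list: module -> list(reactions, species).
#' @export
pathway_modules <- function(net) {
  out <- list()
  for (rx in net$reactions) {
    tags <- grep("^module:", rx$tags, value = TRUE)
    if (length(tags) != 1)
      stop("reaction '", rx$id, "' must carry exactly one module tag")
    mod <- sub("^module:", "", tags)
    if (is.null(out[[mod]])) out[[mod]] <- list(reactions = character(),
                                                species = character())
    out[[mod]]$reactions <- c(out[[mod]]$reactions, rx$id)
    out[[mod]]$species <- unique(c(out[[mod]]$species,
                                   names(rx$reactants), names(rx$products),
                                   rx$modifiers))
  }
  out
}

#' Directional response suite
#'
#' Simulates the canonical single-stimulus experiments (10 ng/mL cytokines;
#' 2% O2; 24 h, plus hypoxia with 10x miR-93 overexpression) on a network
#' and asserts the qualitative direction of every stimulus-target relation
#' encoded in the reference topology: inductions (fold change > 1),
#' repressions (fold change < 1), and miR-93-mediated suppression of
#' hypoxia-induced IL-1beta/IFN-gamma (relative to hypoxia alone).
#'
#' @param net The network under test (defaults to the shipped reference
#'   network).
#' @param settings [solver_settings()].
#' @param state Optional pre-equilibrated resting state.
#' @param t Evaluation time in hours (default 24).
#' @return Data frame with columns stimulus, target, readout, direction
#'   (`"up"`/`"down"`), fold_change, pass.
#' @export
directional_response_suite <- function(net = build_reference_network(),
                                       settings = solver_settings(),
                                       state = NULL, t = 24) {
  if (is.null(state)) state <- equilibrate(net, settings)
  lvl <- "level"; mrna <- "mRNA"; pr <- "production_rate"
  spec <- list(
    IFNG = list(c("iNOS", lvl, "up"), c("CXCL9", lvl, "up"),
                c("CXCL10_m", mrna, "up"), c("IL12", lvl, "up"),
                c("L_VEGFA", pr, "up")),
    IL10 = list(c("L_VEGFA", pr, "down"), c("ARG1", lvl, "up"),
                c("IL1RA", lvl, "up"), c("SOCS3", lvl, "up")),
    IL4 = list(c("ARG1", lvl, "up"), c("IL1RA", lvl, "up"),
               c("L_VEGFA", pr, "up"), c("L_IL10", pr, "up"),
               c("L_TNFA", pr, "down"), c("CXCL10_m", mrna, "down")),
    IL1B = list(c("L_TNFA", pr, "up"), c("CXCL10_m", mrna, "up"),
                c("A20", lvl, "up"), c("SOCS3", lvl, "up"),
                c("miR155", lvl, "up"), c("miR93", lvl, "down")),
    TNFA = list(c("L_TNFA", pr, "up"), c("CXCL10_m", mrna, "up"),
                c("A20", lvl, "up"), c("SOCS3", lvl, "up"),
                c("miR155", lvl, "up"), c("miR93", lvl, "down")),
    Hyp = list(c("iNOS", lvl, "up"), c("L_IL1B", pr, "up"),
               c("L_IFNG", pr, "up"), c("L_TNFA", pr, "up"),
               c("IL12", lvl, "up"), c("ARG1", lvl, "up"),
               c("L_IL10", pr, "up"), c("L_VEGFA", pr, "up"),
               c("IKKb", lvl, "up"), c("HIF1a", lvl, "up"),
               c("HIF2a", lvl, "up"), c("miR93", lvl, "down")))
  conds <- reference_conditions(duration = max(t, 24), pairwise = FALSE)
  rows <- list()
  sims <- list()
  for (nm in names(spec)) {
    sim <- simulate_protocol(net, conds[[nm]], settings, state = state)
    sims[[nm]] <- sim
    for (it in spec[[nm]]) {
      fc <- fold_change(sim, it[1], it[2], t = t)
      pass <- if (it[3] == "up") fc > 1 else fc < 1
      rows[[length(rows) + 1]] <- data.frame(
        stimulus = nm, target = it[1], readout = it[2], direction = it[3],
        fold_change = fc, pass = pass, stringsAsFactors = FALSE)
    }
  }
  # miR-93 overexpression suppresses hypoxia-induced IL-1beta and IFN-gamma
  oe <- stimulation_protocol(oxygen_percent = 2, duration = max(t, 24),
          interventions = list(intervention("k_miR93_syn1", 10),
                               intervention("k_miR93_syn2", 10)),
          name = "Hyp+miR93OE")
  sim_oe <- simulate_protocol(net, oe, settings, state = state)
  for (sp in c("L_IL1B", "L_IFNG")) {
    fc_oe <- fold_change(sim_oe, sp, pr, t = t)
    fc_h <- fold_change(sims[["Hyp"]], sp, pr, t = t)
    rows[[length(rows) + 1]] <- data.frame(
      stimulus = "Hyp+miR93OE", target = sp, readout = pr,
      direction = "down", fold_change = fc_oe / fc_h,
      pass = fc_oe < fc_h, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
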