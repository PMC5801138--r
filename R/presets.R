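# Family presets: the default descriptor-instance list of each in-scope
# family, wired to the shared-intermediate cache. Preset cardinalities:
# ABCIndex 2, AtomCount 16, BalabanJ 1, Chi 56, DetourMatrix 14,
# DistanceMatrix 13, EccentricConnectivityIndex 1, Framework 1,
# KappaShapeIndex 3, MolecularId 12, RingCount 10 (sizes 3-12, extensible),
# WienerIndex 2, ZagrebIndex 4.

# helper: descriptor whose value is one named entry of a multi-value direct
# function evaluated via cached intermediates
pick <- function(lst, nm) {
  if (is_missing(lst)) return(lst)
  lst[[nm]]
}

preset_abc <- function() {
  mk <- function(nm) descriptor("ABCIndex", nm, function(mol, ctx)
    pick(abc_index(mol, dist = if (nm == "ABCGG") ctx$need("dist") else NULL,
                   delta = ctx$need("delta")), nm),
    dependencies = c("delta", if (nm == "ABCGG") "dist"))
  list(mk("ABC"), mk("ABCGG"))
}

preset_atom_count <- function() {
  nms <- c("nAtom", "nHeavyAtom", "nH", "nB", "nC", "nN", "nO", "nS", "nP",
           "nF", "nCl", "nBr", "nI", "nX", "nSpiro", "nBridgehead")
  lapply(nms, function(nm)
    descriptor("AtomCount", nm, function(mol, ctx)
      pick(atom_counts(mol, rings = ctx$need("sssr")), nm),
      dependencies = "sssr"))
}

preset_balaban <- function() {
  list(descriptor("BalabanJ", "BalabanJ", function(mol, ctx)
    balaban_j(mol, dist = ctx$need("dist")), dependencies = "dist"))
}

preset_chi <- function() {
  spec <- rbind(
    expand.grid(kind = "chain", order = 3:7, stringsAsFactors = FALSE),
    expand.grid(kind = "cluster", order = 3:6, stringsAsFactors = FALSE),
    expand.grid(kind = "path_cluster", order = 4:6, stringsAsFactors = FALSE),
    expand.grid(kind = "path", order = 0:7, stringsAsFactors = FALSE)
  )
  tag <- c(chain = "Xch", cluster = "Xc", path_cluster = "Xpc", path = "Xp")
  out <- list()
  mk <- function(kind, order, variant, name) {
    force(kind); force(order); force(variant); force(name)
    descriptor("Chi", name, function(mol, ctx)
      chi(mol, kind, order, variant,
          subgraphs = ctx$need(paste0("subg_", order)),
          delta = ctx$need("delta"), delta_v = ctx$need("delta_v")),
      parameters = list(kind = kind, order = order, variant = variant),
      dependencies = c(paste0("subg_", order), "delta", "delta_v"))
  }
  for (r in seq_len(nrow(spec))) {
    k <- spec$kind[r]; m <- spec$order[r]
    out[[length(out) + 1L]] <- mk(k, m, "simple", sprintf("%s-%dd", tag[k], m))
    out[[length(out) + 1L]] <- mk(k, m, "valence", sprintf("%s-%ddv", tag[k], m))
  }
  for (m in 0:7) {
    out[[length(out) + 1L]] <- mk("path", m, "averaged_simple", sprintf("AXp-%dd", m))
    out[[length(out) + 1L]] <- mk("path", m, "averaged_valence", sprintf("AXp-%ddv", m))
  }
  out
}

preset_detour <- function() {
  nms <- c(paste0(.SPECTRAL_NAMES, "_Dt"), "DetourIndex")
  lapply(nms, function(nm)
    descriptor("DetourMatrix", nm, function(mol, ctx)
      pick(ctx$need("detour_descs"), nm), dependencies = "detour"))
}

preset_distance <- function() {
  nms <- paste0(.SPECTRAL_NAMES, "_D")
  lapply(nms, function(nm)
    descriptor("DistanceMatrix", nm, function(mol, ctx)
      pick(ctx$need("distance_descs"), nm), dependencies = "dist"))
}

preset_eccentric <- function() {
  list(descriptor("EccentricConnectivityIndex", "ECIndex", function(mol, ctx)
    eccentric_connectivity(mol, dist = ctx$need("dist"),
                           delta = ctx$need("delta")),
    dependencies = c("dist", "delta")))
}

preset_framework <- function() {
  list(descriptor("Framework", "fMF", function(mol, ctx) framework_fraction(mol)))
}

preset_kappa <- function() {
  lapply(c("Kier1", "Kier2", "Kier3"), function(nm)
    descriptor("KappaShapeIndex", nm, function(mol, ctx)
      pick(ctx$need("kappa_descs"), nm)))
}

preset_molecular_id <- function() {
  nms <- c("MID", "AMID", "MID_h", "AMID_h", "MID_C", "AMID_C",
           "MID_N", "AMID_N", "MID_O", "AMID_O", "MID_X", "AMID_X")
  lapply(nms, function(nm)
    descriptor("MolecularId", nm, function(mol, ctx)
      pick(molecular_id(mol, weights = ctx$need("mid_w")), nm),
      dependencies = "mid_w"))
}

preset_ring_count <- function(max_n = 12L) {
  if (max_n < 12L) stop("max_n must be >= 12")
  lapply(3:max_n, function(s)
    descriptor("RingCount", paste0("nRing", s), function(mol, ctx)
      pick(ring_counts(mol, sizes = s, rings = ctx$need("sssr")), paste0("nRing", s)),
      parameters = list(size = s), dependencies = "sssr"))
}

preset_wiener <- function() {
  lapply(c("WPath", "WPol"), function(nm)
    descriptor("WienerIndex", nm, function(mol, ctx)
      pick(wiener(mol, dist = ctx$need("dist")), nm), dependencies = "dist"))
}

preset_zagreb <- function() {
  lapply(c("Zagreb1", "Zagreb2", "mZagreb1", "mZagreb2"), function(nm)
    descriptor("ZagrebIndex", nm, function(mol, ctx)
      pick(zagreb_indices(mol, delta = ctx$need("delta")), nm),
      dependencies = "delta"))
}

preset_registry <- function() {
  list(
    ABCIndex = preset_abc,
    AtomCount = preset_atom_count,
    BalabanJ = preset_balaban,
    Chi = preset_chi,
    DetourMatrix = preset_detour,
    DistanceMatrix = preset_distance,
    EccentricConnectivityIndex = preset_eccentric,
    Framework = preset_framework,
    KappaShapeIndex = preset_kappa,
    MolecularId = preset_molecular_id,
    RingCount = preset_ring_count,
    WienerIndex = preset_wiener,
    ZagrebIndex = preset_zagreb
  )
}
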