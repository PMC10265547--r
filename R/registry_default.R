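# The built-in 68-bundle virtual-dissection protocol.
#
# The protocol structure (bundle names, groups, hemisphere layout, include /
# exclude logic) is exact; the VOIs are expressed in a symbolic label
# vocabulary (see protocol_label_names()) bound to the miniature phantom
# atlas shipped with the package.  Real atlas label ids (FreeSurfer, MSBP,
# UKBB, SUIT, PD25 ...) can be transcribed into a registry JSON file and
# loaded with load_registry(path), overriding the symbolic bindings.
#
# Census: 15 bilateral association families (x2 hemispheres = 30),
# 8 commissural, 12 bilateral projection families (x2 = 24), 3 bilateral
# cerebellar families (x2 = 6) -> 68.  The posterior thalamic radiation is
# an alias of OR_OL and is not a separate entry.

#' Symbolic region vocabulary of the default protocol
#'
#' Region names used by the built-in registry's `labels` VOIs.  Bilateral
#' regions carry `_L`/`_R` suffixes; `brainstem` and `optic_chiasm` are
#' midline.  The phantom atlas ([atlas_parcellation()]) provides a label
#' table resolving every one of these names.
#'
#' @return character vector of region names.
#' @export
protocol_label_names <- function() {
  bilateral <- c("frontal", "prefrontal", "premotor", "SMA", "motor",
                 "sensory", "parietal", "occipital", "temporal", "cingulate",
                 "hippocampus", "thalamus", "cerebellum")
  c(paste0(rep(bilateral, each = 2), c("_L", "_R")),
    "brainstem", "optic_chiasm")
}

lab <- function(...) voi_spec("labels", labels = c(...))

# one bilateral pair from per-hemisphere recipes
bilateral_pair <- function(family, group, make) {
  lapply(c("left", "right"), function(hemi) {
    s <- if (hemi == "left") "_L" else "_R"
    o <- if (hemi == "left") "_R" else "_L"   # contralateral suffix
    args <- make(s, o)
    do.call(bundle_definition,
            c(list(name = paste0(family, s), group = group,
                   hemisphere = hemi), args))
  })
}

commissural_def <- function(name, left_label, right_label,
                            thickness_mm = 4) {
  bundle_definition(
    name = name, group = "commissural", hemisphere = "midline",
    includes = list(lab(left_label), lab(right_label),
                    voi_spec("midsagittal", thickness_mm = thickness_mm)))
}

#' The built-in 68-bundle dissection protocol
#'
#' Constructs the full default registry: 15 bilateral association bundle
#' families, 8 commissural bundles (anterior commissure plus the corpus
#' callosum in 7 segments), 12 bilateral projection families and 3 bilateral
#' cerebellar families.
#'
#' @return a [bundle_registry()] of exactly 68 definitions.
#' @export
default_registry <- function() {
  defs <- list()
  add <- function(x) defs[[length(defs) + 1L]] <<- x
  add2 <- function(lst) for (d in lst) add(d)

  # -- association (15 families x 2) ---------------------------------------
  add2(bilateral_pair("AF", "association", function(s, o) list(
    includes = list(lab(paste0("frontal", s)), lab(paste0("temporal", s))),
    excludes = list(lab(paste0("motor", s))))))
  add2(bilateral_pair("CCing", "association", function(s, o) list(
    includes = list(lab(paste0("cingulate", s)), lab(paste0("frontal", s))),
    excludes = list(lab(paste0("temporal", s))))))
  add2(bilateral_pair("TCing", "association", function(s, o) list(
    includes = list(lab(paste0("cingulate", s)), lab(paste0("temporal", s))))))
  add2(bilateral_pair("FX", "association", function(s, o) list(
    includes = list(lab(paste0("hippocampus", s)), lab(paste0("thalamus", s))))))
  add2(bilateral_pair("FAT", "association", function(s, o) list(
    includes = list(lab(paste0("frontal", s)), lab(paste0("SMA", s))))))
  add2(bilateral_pair("IFOF", "association", function(s, o) list(
    includes = list(lab(paste0("frontal", s)), lab(paste0("occipital", s))),
    excludes = list(lab(paste0("temporal", s))))))
  add2(bilateral_pair("ILF", "association", function(s, o) list(
    includes = list(lab(paste0("temporal", s)), lab(paste0("occipital", s))))))
  add2(bilateral_pair("MdLF", "association", function(s, o) list(
    includes = list(lab(paste0("temporal", s)), lab(paste0("parietal", s))))))
  for (fam in c("SLF_whole", "SLF_I", "SLF_IId", "SLF_IIv", "SLF_III")) {
    add2(bilateral_pair(fam, "association", function(s, o) list(
      includes = list(lab(paste0("frontal", s)), lab(paste0("parietal", s))),
      excludes = list(lab(paste0("temporal", s))))))
  }
  add2(bilateral_pair("UF", "association", function(s, o) list(
    includes = list(lab(paste0("frontal", s)), lab(paste0("temporal", s))),
    excludes = list(lab(paste0("parietal", s), paste0("occipital", s))))))
  add2(bilateral_pair("VOF", "association", function(s, o) list(
    includes = list(lab(paste0("occipital", s)), lab(paste0("parietal", s))),
    excludes = list(lab(paste0("frontal", s))))))

  # -- commissural (8) -----------------------------------------------------
  add(commissural_def("AC", "temporal_L", "temporal_R"))
  add(commissural_def("CC_PreF", "prefrontal_L", "prefrontal_R"))
  add(commissural_def("CC_PMC_SMA", "premotor_L", "premotor_R"))
  add(commissural_def("CC_Motor", "motor_L", "motor_R"))
  add(commissural_def("CC_Sensory", "sensory_L", "sensory_R"))
  add(commissural_def("CC_Parietal", "parietal_L", "parietal_R"))
  add(commissural_def("CC_Occipital", "occipital_L", "occipital_R"))
  add(commissural_def("CC_Temporal", "temporal_L", "temporal_R"))

  # -- projection (12 families x 2) ----------------------------------------
  add2(bilateral_pair("ML", "projection", function(s, o) list(
    includes = list(lab("brainstem"), lab(paste0("thalamus", s))))))
  add2(bilateral_pair("OT", "projection", function(s, o) list(
    includes = list(lab("optic_chiasm"), lab(paste0("thalamus", s))))))
  add2(bilateral_pair("OR", "projection", function(s, o) list(
    includes = list(lab(paste0("thalamus", s)), lab(paste0("occipital", s))),
    excludes = list(lab(paste0("frontal", s))))))
  # OR_OL: extended optic radiation to the whole occipital lobe; also serves
  # as the posterior thalamic radiation (PoTR), which is not a separate entry.
  add2(bilateral_pair("OR_OL", "projection", function(s, o) list(
    includes = list(lab(paste0("thalamus", s)), lab(paste0("occipital", s))))))
  add2(bilateral_pair("PyT_all", "projection", function(s, o) list(
    includes = list(lab("brainstem"),
                    lab(paste0("motor", s), paste0("premotor", s),
                        paste0("SMA", s))))))
  add2(bilateral_pair("CST", "projection", function(s, o) list(
    includes = list(lab("brainstem"),
                    lab(paste0("motor", s), paste0("sensory", s))))))
  add2(bilateral_pair("M1_CST", "projection", function(s, o) list(
    includes = list(lab("brainstem"), lab(paste0("motor", s))))))
  add2(bilateral_pair("PyT_PMC", "projection", function(s, o) list(
    includes = list(lab("brainstem"), lab(paste0("premotor", s))))))
  add2(bilateral_pair("PyT_SMA", "projection", function(s, o) list(
    includes = list(lab("brainstem"), lab(paste0("SMA", s))))))
  add2(bilateral_pair("ATR", "projection", function(s, o) list(
    includes = list(lab(paste0("thalamus", s)), lab(paste0("prefrontal", s))),
    excludes = list(lab(paste0("occipital", s))))))
  add2(bilateral_pair("STR", "projection", function(s, o) list(
    includes = list(lab(paste0("thalamus", s)),
                    lab(paste0("motor", s), paste0("sensory", s))))))
  add2(bilateral_pair("PaTR", "projection", function(s, o) list(
    includes = list(lab(paste0("thalamus", s)), lab(paste0("parietal", s))))))

  # -- cerebellar (3 families x 2) -----------------------------------------
  add2(bilateral_pair("DRTT", "cerebellar", function(s, o) list(
    includes = list(lab(paste0("cerebellum", s)), lab("brainstem"),
                    lab(paste0("thalamus", o))))))
  add2(bilateral_pair("ICP", "cerebellar", function(s, o) list(
    includes = list(lab(paste0("cerebellum", s)), lab("brainstem")))))
  add2(bilateral_pair("MCP", "cerebellar", function(s, o) list(
    includes = list(lab(paste0("cerebellum", s)), lab("brainstem"),
                    lab(paste0("cerebellum", o))))))

  bundle_registry(defs, version = "wmtract-protocol-1")
}
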