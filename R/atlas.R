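#' Atlas specification
#'
#' Bundles the gray-matter parcellation (unilateral regions with left/right
#' homologue pairing and a functional-network label) together with the
#' white-matter target regions (name, anatomical tract family, volume).
#' The gray-matter side drives FC construction and regional importance
#' aggregation; the white-matter side names the FA prediction targets and
#' supplies the grouping factor for the tract-clustering test.
#'
#' @param gray data.frame with columns `name`, `hemi` ("L"/"R"), `pair_id`
#'   (integer identifying homologue pairs) and `network`.
#' @param wm data.frame with columns `name`, `tract` and `volume_cm3`.
#'
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(gray, wm) {
  need_g <- c("name", "hemi", "pair_id", "network")
  need_w <- c("name", "tract", "volume_cm3")
  if (!all(need_g %in% names(gray)))
    stop("gray atlas table needs columns: ", paste(need_g, collapse = ", "))
  if (!all(need_w %in% names(wm)))
    stop("wm atlas table needs columns: ", paste(need_w, collapse = ", "))
  if (anyDuplicated(gray$name)) stop("duplicated gray region names")
  if (anyDuplicated(wm$name)) stop("duplicated white-matter region names")
  # pairing must be a perfect matching: every pair_id has exactly one L and one R
  tab <- table(gray$pair_id, gray$hemi)
  if (!all(dim(tab) == c(nrow(gray) / 2, 2)) || !all(tab == 1))
    stop("gray pairing is not a perfect left/right matching")
  if (any(is.na(wm$tract))) stop("every white-matter region needs a tract group")
  gray <- gray[order(gray$pair_id, gray$hemi), , drop = FALSE]
  structure(list(gray = gray, wm = wm), class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf(
    "Atlas: %d unilateral gray regions (%d bilateral pairs, %d networks); %d white-matter regions (%d tracts)\n",
    nrow(x$gray), nrow(x$gray) / 2, length(unique(x$gray$network)),
    nrow(x$wm), length(unique(x$wm$tract))
  ))
  invisible(x)
}

#' Bilateral region names of an atlas
#' @param atlas an `atlas_spec`.
#' @return Character vector, one name per homologue pair, in `pair_id` order.
#' @export
bilateral_names <- function(atlas) {
  g <- atlas$gray
  left <- g[g$hemi == "L", ]
  left <- left[order(left$pair_id), ]
  sub("_L$", "", left$name)
}

#' Homologue pairing of an atlas
#' @param atlas an `atlas_spec`.
#' @return data.frame with columns `left`, `right`, `name` (bilateral name).
#' @export
atlas_pairing <- function(atlas) {
  g <- atlas$gray
  l <- g[g$hemi == "L", ]; l <- l[order(l$pair_id), ]
  r <- g[g$hemi == "R", ]; r <- r[order(r$pair_id), ]
  data.frame(left = l$name, right = r$name, name = bilateral_names(atlas),
             stringsAsFactors = FALSE)
}

# The 27 skeleton white-matter target regions (JHU-Mori nomenclature after
# hemispheric averaging) with their anatomical tract families.
.wm_region_table <- function() {
  regions <- c(
    "Middle cerebellar peduncle"        , "Brainstem",
    "Pontine crossing tract"            , "Brainstem",
    "Inferior cerebellar peduncle"      , "Brainstem",
    "Superior cerebellar peduncle"      , "Brainstem",
    "Medial lemniscus"                  , "Brainstem",
    "Genu of corpus callosum"           , "Commissural",
    "Body of corpus callosum"           , "Commissural",
    "Splenium of corpus callosum"       , "Commissural",
    "Tapetum"                           , "Commissural",
    "Corticospinal tract"               , "Corticospinal",
    "Cerebral peduncle"                 , "Corticospinal",
    "Anterior limb of internal capsule" , "Corticospinal",
    "Posterior limb of internal capsule", "Corticospinal",
    "Retrolenticular part of internal capsule", "Corticospinal",
    "Anterior corona radiata"           , "Corticospinal",
    "Superior corona radiata"           , "Corticospinal",
    "Posterior corona radiata"          , "Corticospinal",
    "Posterior thalamic radiation"      , "Corticospinal",
    "Sagittal stratum"                  , "Fasciculi",
    "External capsule"                  , "Fasciculi",
    "Superior longitudinal fasciculus"  , "Fasciculi",
    "Superior fronto-occipital fasciculus", "Fasciculi",
    "Uncinate fasciculus"               , "Fasciculi",
    "Fornix"                            , "Limbic",
    "Cingulum (cingulate gyrus)"        , "Limbic",
    "Cingulum (hippocampus)"            , "Limbic",
    "Fornix (cres) / Stria terminalis"  , "Limbic"
  )
  m <- matrix(regions, ncol = 2, byrow = TRUE)
  data.frame(name = m[, 1], tract = m[, 2], stringsAsFactors = FALSE)
}

.network_names <- c("Default", "Frontoparietal", "DorsalAttention",
                    "VentralAttention", "Limbic", "Somatomotor",
                    "Visual", "Subcortical")

#' Build a synthetic atlas
#'
#' Constructs an `atlas_spec` for simulation studies: `n_gray_unilateral`
#' gray regions paired into left/right homologues with network labels cycling
#' over eight canonical functional networks, and `n_wm` white-matter targets.
#' When `n_wm = 27` the standard skeleton region names and tract families are
#' used; otherwise generic names are generated and tracts assigned in blocks.
#' Volumes are synthetic (log-normal around a few cubic centimetres).
#'
#' @param n_gray_unilateral even count of unilateral gray regions (default 106).
#' @param n_wm number of white-matter target regions (default 27).
#' @param seed RNG seed for the synthetic volumes.
#' @return An `atlas_spec`.
#' @export
synthetic_atlas <- function(n_gray_unilateral = 106, n_wm = 27, seed = 1) {
  if (n_gray_unilateral < 2 || n_gray_unilateral %% 2 != 0)
    stop("n_gray_unilateral must be an even count >= 2")
  R <- n_gray_unilateral / 2
  base <- sprintf("G%03d", seq_len(R))
  gray <- data.frame(
    name = c(paste0(base, "_L"), paste0(base, "_R")),
    hemi = rep(c("L", "R"), each = R),
    pair_id = rep(seq_len(R), 2),
    network = rep(rep_len(.network_names, R), 2),
    stringsAsFactors = FALSE
  )
  if (n_wm == 27) {
    wm <- .wm_region_table()
  } else {
    fams <- c("Brainstem", "Commissural", "Corticospinal", "Fasciculi", "Limbic")
    wm <- data.frame(
      name = sprintf("WM%02d", seq_len(n_wm)),
      tract = rep_len(rep(fams, each = max(1, ceiling(n_wm / length(fams)))), n_wm),
      stringsAsFactors = FALSE
    )
  }
  rng <- local_rng(seed)
  wm$volume_cm3 <- round(exp(stats::rnorm(nrow(wm), mean = log(4), sd = 0.6)), 3)
  restore_rng(rng)
  atlas_spec(gray, wm)
}

#' Read an atlas from delimited files
#'
#' @param gray_file path to a delimited table with columns
#'   `name,hemi,pair_id,network`.
#' @param wm_file path to a delimited table with columns
#'   `name,tract,volume_cm3`.
#' @return An `atlas_spec`.
#' @export
read_atlas <- function(gray_file, wm_file) {
  atlas_spec(read_table_auto(gray_file), read_table_auto(wm_file))
}

#' Write an atlas to delimited files
#' @param atlas an `atlas_spec`.
#' @param gray_file,wm_file output paths (tab-separated).
#' @return Invisibly, the atlas.
#' @export
write_atlas <- function(atlas, gray_file, wm_file) {
  utils::write.table(atlas$gray, gray_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(atlas$wm, wm_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(atlas)
}
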