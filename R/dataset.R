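#' Species means from individual-level brain records
#'
#' Averages raw masses per species; log transforms are applied afterwards by
#' [build_brain_table()], so means are arithmetic means of masses, not of
#' logs.
#'
#' @param records Data frame with columns `species` and any of `cx`, `cb`,
#'   `brain`, `body` (masses, g or kg, all > 0 where present).
#' @return Data frame with one row per species: mean masses and
#'   `n_individuals`.
#' @export
species_means <- function(records) {
  stopifnot(is.data.frame(records), "species" %in% names(records))
  vars <- intersect(c("cx", "cb", "brain", "body"), names(records))
  if (length(vars) == 0) stop("no mass columns found among cx/cb/brain/body")
  for (v in vars) {
    bad <- !is.na(records[[v]]) & records[[v]] <= 0
    if (any(bad))
      stop("non-positive ", v, " mass for species ",
           paste(unique(records$species[bad]), collapse = ", "))
  }
  sp <- sort(unique(as.character(records$species)))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (v in vars)
    out[[v]] <- vapply(sp, function(s)
      mean(records[[v]][records$species == s], na.rm = TRUE), numeric(1))
  out$n_individuals <- vapply(sp, function(s)
    sum(records$species == s), integer(1))
  for (v in vars) out[[v]][is.nan(out[[v]])] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Flag species whose components exhaust total brain mass
#'
#' A species whose cerebrum + cerebellum equals (or exceeds, within a relative
#' tolerance) total brain mass has no measurable rest-of-brain, which
#' indicates one or both component measurements include additional
#' structures; such species are excluded rather than given RoB near zero.
#'
#' @param species Data frame with columns `species`, `cx`, `cb`, `brain`.
#' @param tol Relative tolerance on the RoB fraction `(brain - cx - cb)/brain`
#'   below which a species is excluded (default `1e-3`; exact equality is the
#'   canonical case, the tolerance guards rounded inputs).
#' @return Data frame `species`, `keep` (logical), `rob_fraction`, `reason`.
#' @export
validate_components <- function(species, tol = 1e-3) {
  stopifnot(all(c("species", "cx", "cb", "brain") %in% names(species)))
  if (any(species$brain <= 0, na.rm = TRUE))
    stop("non-positive brain mass")
  frac <- (species$brain - species$cx - species$cb) / species$brain
  keep <- is.na(frac) | frac > tol
  reason <- ifelse(keep, "",
                   "CX + CB equals total brain mass (RoB <= tolerance)")
  data.frame(species = species$species, keep = keep, rob_fraction = frac,
             reason = reason, stringsAsFactors = FALSE)
}

#' Rest-of-brain mass
#'
#' RoB = brain - CX - CB, minus olfactory bulb mass where measured. Olfactory
#' bulbs are excluded from RoB because the olfactory system is absent or
#' vestigial in toothed whales, which would otherwise deflate terrestrial RoB
#' relative to cetacean RoB and mimic a grade shift.
#'
#' @param brain,cx,cb Masses (same units, > 0); vectorized.
#' @param olfactory_bulb Optional olfactory bulb mass subtracted where
#'   available (default 0).
#' @return RoB masses.
#' @export
compute_rob <- function(brain, cx, cb, olfactory_bulb = 0) {
  rob <- brain - cx - cb - olfactory_bulb
  if (any(rob <= 0, na.rm = TRUE))
    stop("RoB <= 0 for some species; run validate_components() and exclude ",
         "species whose components exhaust total brain mass")
  rob
}

#' Assemble the per-species analysis table
#'
#' Applies the exclusion rule, builds RoB, takes log10 of all masses and
#' attaches taxon-group flags.
#'
#' @param species_means Data frame from [species_means()] (columns `species`,
#'   `cx`, `cb`, `brain`, optionally `body`, `olfactory_bulb`,
#'   `n_individuals`).
#' @param group_map Data frame with column `species` plus logical flag columns
#'   (e.g. `is_cetacean`, `is_mysticete`, `is_primate`, `is_marsupial`)
#'   covering every species.
#' @param tol Exclusion tolerance passed to [validate_components()].
#' @return Data frame with `log_cx`, `log_cb`, `log_brain`, `log_rob`,
#'   optional `log_body`, group flags, and `n_individuals`; attribute
#'   `"exclusions"` records dropped species with reasons.
#' @export
build_brain_table <- function(species_means, group_map = NULL, tol = 1e-3) {
  val <- validate_components(species_means, tol = tol)
  excluded <- val[!val$keep, c("species", "reason")]
  tab <- species_means[val$keep, , drop = FALSE]
  ob <- if ("olfactory_bulb" %in% names(tab))
    ifelse(is.na(tab$olfactory_bulb), 0, tab$olfactory_bulb) else 0
  out <- data.frame(species = tab$species,
                    log_cx = log10(tab$cx),
                    log_cb = log10(tab$cb),
                    log_brain = log10(tab$brain),
                    log_rob = log10(compute_rob(tab$brain, tab$cx, tab$cb, ob)),
                    stringsAsFactors = FALSE)
  if ("body" %in% names(tab)) out$log_body <- log10(tab$body)
  out$n_individuals <- if ("n_individuals" %in% names(tab))
    tab$n_individuals else 1L
  if (!is.null(group_map)) {
    stopifnot("species" %in% names(group_map))
    missing_sp <- setdiff(out$species, group_map$species)
    if (length(missing_sp) > 0)
      stop("group_map lacks species: ", paste(missing_sp, collapse = ", "))
    out <- merge(out, group_map, by = "species", sort = FALSE)
  }
  attr(out, "exclusions") <- excluded
  out
}

#' Merge brain, ecological and tree species sets
#'
#' Inner join of the brain table and ecological covariates restricted to
#' species present as tree tips; every dropped species is logged with the
#' reason for the drop.
#'
#' @param brain Brain table from [build_brain_table()].
#' @param eco Optional data frame of ecological covariates keyed by `species`.
#' @param tree A `phylo` tree whose tip labels are species ids.
#' @return Data frame of the joined rows; attribute `"drop_log"` is a data
#'   frame (`species`, `reason`).
#' @export
merge_traits <- function(brain, eco = NULL, tree = NULL) {
  stopifnot(is.data.frame(brain), "species" %in% names(brain))
  drops <- data.frame(species = character(), reason = character(),
                      stringsAsFactors = FALSE)
  out <- brain
  if (!is.null(tree)) {
    off_tree <- setdiff(out$species, tree$tip.label)
    if (length(off_tree) > 0)
      drops <- rbind(drops, data.frame(species = off_tree,
                                       reason = "not a tree tip"))
    out <- out[out$species %in% tree$tip.label, , drop = FALSE]
  }
  if (!is.null(eco)) {
    stopifnot("species" %in% names(eco))
    no_eco <- setdiff(out$species, eco$species)
    if (length(no_eco) > 0)
      drops <- rbind(drops, data.frame(species = no_eco,
                                       reason = "no ecological data"))
    out <- merge(out, eco, by = "species", sort = FALSE)
  }
  if (nrow(out) == 0)
    stop("no species shared between the brain table, ecological table and tree")
  attr(out, "drop_log") <- drops
  out
}
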