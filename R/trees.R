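#' Read a phylogenetic tree from Newick or Nexus
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that accepts a
#' file path or a literal tree string, insists on branch lengths, and returns a
#' standard `phylo` object with unique tip labels.
#'
#' @param source Path to a tree file, or a character string containing the tree
#'   itself (Newick text, or a Nexus block for `format = "nexus"`).
#' @param format `"auto"` (default; sniffed from the content), `"newick"`, or
#'   `"nexus"`.
#' @return A rooted `phylo` object with branch lengths.
#' @export
read_tree <- function(source, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1L)
  is_file <- !grepl("[(;]", source) && file.exists(source)
  txt <- if (is_file) paste(readLines(source, warn = FALSE), collapse = "\n") else source
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "newick"
  }
  if (format == "newick") .check_newick(txt)
  tf <- tempfile(fileext = ".tre")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  tree <- if (format == "nexus") ape::read.nexus(tf) else ape::read.tree(tf)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse tree from ", if (is_file) source else "text input")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; dated branch lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

# cheap structural check so malformed Newick fails with a position
.check_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  invisible(TRUE)
}

#' Write a tree to Newick or Nexus
#'
#' @param tree A `phylo` object.
#' @param path Output path; if `NULL` the serialized text is returned.
#' @param format `"newick"` or `"nexus"`.
#' @return `path` invisibly, or the tree text when `path` is `NULL`.
#' @export
write_tree <- function(tree, path = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) {
    if (format == "nexus") {
      tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
      ape::write.nexus(tree, file = tf)
      return(paste(readLines(tf), collapse = "\n"))
    }
    return(ape::write.tree(tree))
  }
  if (format == "nexus") ape::write.nexus(tree, file = path)
  else ape::write.tree(tree, file = path)
  invisible(path)
}

#' Root-to-node depths
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of root-to-node path lengths for all nodes
#'   (tips first, in ape id order).
#' @export
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Test whether a tree is ultrametric within a tolerance
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on the spread of root-to-tip depths, in the
#'   tree's branch-length units (default `1e-6`).
#' @return Logical flag.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

#' Splice a dated donor clade into a backbone tree
#'
#' Replaces the clade of `backbone` spanned by `anchor_taxa` with the
#' corresponding subtree of `donor`, multiplying every donor branch by the
#' ratio of the anchor clade's crown age in the backbone to its crown age in
#' the donor, so that divergence dates line up across the junction. The branch
#' above the spliced clade is set so node ages remain continuous; the
#' adjustment applied to it is reported in the `splice` attribute rather than
#' silently absorbed.
#'
#' @param backbone Dated `phylo` tree containing the clade to replace.
#' @param donor Dated `phylo` tree supplying the replacement topology; its tips
#'   must include every tip of the replaced clade.
#' @param anchor_taxa Character vector of species ids defining the clade. The
#'   clade must be monophyletic in the backbone.
#' @return A `phylo` tree with attribute `"splice"` (list: `ratio`,
#'   `backbone_age`, `donor_age`, `stem_adjustment`).
#' @export
splice_clade <- function(backbone, donor, anchor_taxa) {
  stopifnot(inherits(backbone, "phylo"), inherits(donor, "phylo"))
  anchor_taxa <- as.character(anchor_taxa)
  miss <- setdiff(anchor_taxa, backbone$tip.label)
  if (length(miss) > 0)
    stop("anchor taxa not in backbone: ", paste(miss, collapse = ", "))
  ntip_bk <- ape::Ntip(backbone)
  bk_node <- if (length(anchor_taxa) == 1L) match(anchor_taxa, backbone$tip.label)
             else ape::getMRCA(backbone, anchor_taxa)
  clade_tips <- if (bk_node <= ntip_bk) backbone$tip.label[bk_node]
                else ape::extract.clade(backbone, bk_node)$tip.label
  if (!setequal(clade_tips, anchor_taxa))
    stop("anchor clade is not monophyletic in backbone; its MRCA also spans: ",
         paste(setdiff(clade_tips, anchor_taxa), collapse = ", "))
  dn_tips <- intersect(donor$tip.label, clade_tips)
  if (!all(clade_tips %in% donor$tip.label))
    stop("donor tree lacks tips of the replaced clade: ",
         paste(setdiff(clade_tips, donor$tip.label), collapse = ", "))
  dn_node <- if (length(dn_tips) == ape::Ntip(donor)) ape::Ntip(donor) + 1L
             else ape::getMRCA(donor, dn_tips)
  dn_clade <- if (dn_node == ape::Ntip(donor) + 1L) donor
              else ape::extract.clade(donor, dn_node)

  # crown ages measured as subtree height (max depth below the node)
  age_bk <- max(node_depths(backbone)) - node_depths(backbone)[bk_node]
  age_dn <- max(node_depths(dn_clade))
  if (age_dn <= 0) stop("anchor clade LCA has age zero in donor tree")
  ratio <- age_bk / age_dn
  dn_clade$edge.length <- dn_clade$edge.length * ratio

  # reduce backbone clade to one placeholder tip, then graft the donor subtree
  stem_edge <- which(backbone$edge[, 2] == bk_node)
  stem_orig <- if (length(stem_edge) == 1L) backbone$edge.length[stem_edge]
               else NA_real_
  placeholder <- ".splice_placeholder."
  pruned <- ape::drop.tip(backbone, setdiff(clade_tips, clade_tips[1L]))
  ph_tip <- match(clade_tips[1L], pruned$tip.label)
  pruned$tip.label[ph_tip] <- placeholder
  ph_edge <- which(pruned$edge[, 2] == ph_tip)
  ph_len <- pruned$edge.length[ph_edge]
  parent_depth <- node_depths(pruned)[pruned$edge[ph_edge, 1]]
  parent_age <- max(node_depths(pruned)) - parent_depth
  stem_new <- parent_age - age_bk # donor subtree now has height age_bk
  if (stem_new < 0)
    stop("rescaled donor clade is older than its attachment point in backbone")
  dn_clade$root.edge <- stem_new
  out <- ape::bind.tree(pruned, dn_clade, where = ph_tip, position = ph_len)
  # bind.tree at position=len attaches at the stem parent; the placeholder is
  # then removed together with its branch
  out <- ape::drop.tip(out, placeholder)
  attr(out, "splice") <- list(ratio = ratio, backbone_age = age_bk,
                              donor_age = age_dn,
                              stem_adjustment = stem_new - stem_orig)
  out
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' `V[i, j]` is the root-to-MRCA shared path length of tips `i` and `j`
#' (diagonal = root-to-tip depth), the expected trait covariance under
#' unit-rate Brownian motion.
#'
#' @param tree A `phylo` object.
#' @param taxa_order Optional character vector giving the row/column order;
#'   defaults to the tree's tip labels.
#' @return A `phylo_vcv` object: list with `V` (named matrix), `taxa`, and
#'   `lambda` (initialized to 1).
#' @export
phylo_vcv <- function(tree, taxa_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  V <- ape::vcv.phylo(tree)
  if (is.null(taxa_order)) taxa_order <- tree$tip.label
  unknown <- setdiff(taxa_order, rownames(V))
  if (length(unknown) > 0)
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  V <- V[taxa_order, taxa_order, drop = FALSE]
  structure(list(V = V, taxa = taxa_order, lambda = 1),
            class = "phylo_vcv")
}

#' Pagel's lambda transformation of a phylogenetic covariance
#'
#' Multiplies off-diagonal entries by `lam`, leaving tip variances unchanged;
#' `lam = 1` is full Brownian covariance, `lam = 0` a star phylogeny.
#'
#' @param vcv A `phylo_vcv` object.
#' @param lam Signal strength in `[0, 1]`.
#' @return The transformed `phylo_vcv`, with `lambda` set to
#'   `lam * previous lambda`.
#' @export
apply_lambda <- function(vcv, lam) {
  stopifnot(inherits(vcv, "phylo_vcv"), is.numeric(lam), length(lam) == 1L)
  if (is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must lie in [0, 1], got ", lam)
  d <- diag(vcv$V)
  vcv$V <- vcv$V * lam
  diag(vcv$V) <- d
  vcv$lambda <- vcv$lambda * lam
  vcv
}

# lambda as a branch-length transform: internal edges * lam, tip edges
# stretched to keep depths; equivalent to apply_lambda on the implied V
.lambda_edge_lengths <- function(tree, lam) {
  ntip <- ape::Ntip(tree)
  depths <- node_depths(tree)
  el <- tree$edge.length * lam
  tip_edge <- tree$edge[, 2] <= ntip
  el[tip_edge] <- tree$edge.length[tip_edge] * lam +
    (1 - lam) * depths[tree$edge[tip_edge, 2]]
  el
}
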