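#' @title Unified heatmap layout (uniHM)
#' @description Classical per-gene z-scoring destroys the common reference
#'   origin of expression: zero expression maps to a different negative
#'   display value for every gene, so colour no longer ranks signature
#'   quality. The unified layout instead (1) projects each gene onto the
#'   scatter simplex by dividing by the sum of its group means in linear
#'   space, (2) standardizes in log space with group-balanced statistics so
#'   zero expression maps to one common clamped origin for all genes, and
#'   (3) orders rows and columns by cosine score against the SG/DSG
#'   references, so display contrast is consistent with signature quality.
#' @name unihm
NULL

#' Perspective projection onto the scatter simplex
#'
#' Each cell of gene i is divided by the sum over groups of the gene's
#' group-mean expression \eqn{\sum_k \bar x_k(i)} (linear space), so the
#' projected per-gene group means sum to exactly 1. Genes whose group-mean
#' sum is zero or not computable are dropped with a warning.
#'
#' @param m an `omics_matrix` in linear space (log2 input converted with
#'   `pseudo`).
#' @param g a [group_labels()] object.
#' @param pseudo pseudo-count for log2 inputs.
#' @return A genes x samples matrix of projected values (masked cells NA),
#'   with the projected group means attached as `attr(, "group_means")`.
#' @export
simplex_project <- function(m, g, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), inherits(g, "group_labels"))
  work <- ensure_space(m, "linear", pseudo)
  grp <- match_labels(work, g)
  v <- observed_values(work)
  st <- group_stats(v, grp, g$groups)
  denom <- rowSums(st$mean)
  bad <- is.na(denom) | denom <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) dropped: zero or undefined group-mean sum")
    v <- v[!bad, , drop = FALSE]
    st$mean <- st$mean[!bad, , drop = FALSE]
    denom <- denom[!bad]
  }
  proj <- v / denom
  attr(proj, "group_means") <- st$mean / denom
  proj
}

#' Log-space display standardization with a common origin
#'
#' Projected values are clamped below at `floor`, log2-transformed, and
#' per gene standardized by the mean of the K log-space group means
#' (groups weighted equally regardless of size) and the pooled
#' within-group log-space SD. Because the clamp floor is shared across
#' genes, zero expression maps to the same display value everywhere — the
#' common-origin property that classical per-gene z-scoring lacks. Genes
#' with zero pooled SD are rendered as all-zeros and flagged.
#'
#' @param projected matrix from [simplex_project()] (values >= 0).
#' @param g a [group_labels()] object.
#' @param floor positive clamp; default half the smallest positive
#'   projected value (shared across genes).
#' @return The standardized display matrix; `attr(, "flat_genes")` lists
#'   genes with zero pooled SD, `attr(, "floor")` the clamp used.
#' @export
display_standardize <- function(projected, g, floor = NULL) {
  stopifnot(is.matrix(projected))
  if (any(projected < 0, na.rm = TRUE))
    stop("projected values must be nonnegative")
  if (is.null(floor)) {
    pos <- projected[!is.na(projected) & projected > 0]
    if (length(pos) == 0) stop("no positive projected value to set the floor")
    floor <- min(pos) / 2
  }
  if (floor <= 0) stop("floor must be positive")
  grp <- g$assignment[colnames(projected)]
  if (anyNA(grp)) stop("samples without a group label in projected matrix")
  L <- log2(pmax(projected, floor))
  st <- group_stats(L, grp, g$groups)
  center <- rowMeans(st$mean, na.rm = TRUE)
  # pooled within-group SD: residuals around each sample's own group mean
  resid2 <- (L - st$mean[, match(grp, g$groups), drop = FALSE])^2
  nobs <- rowSums(!is.na(L))
  K_eff <- rowSums(!is.na(st$mean))
  df <- pmax(nobs - K_eff, 1)
  pooled <- sqrt(rowSums(resid2, na.rm = TRUE) / df)
  flat <- !is.na(pooled) & pooled == 0
  disp <- (L - center) / pooled
  disp[flat, ] <- 0
  disp[is.na(disp)] <- 0
  attr(disp, "flat_genes") <- rownames(projected)[flat]
  attr(disp, "floor") <- floor
  # clamped log matrix: the stage at which zero expression sits at the one
  # shared origin log2(floor) for every gene
  attr(disp, "log_clamped") <- L
  disp
}

#' Classical per-gene z-score standardization (comparator)
#'
#' The conventional heatmap transform: each gene centered by its mean and
#' scaled by its SD across samples. Provided to demonstrate the defect the
#' unified layout fixes: zero expression lands on a different (floating,
#' negative) display value for each gene.
#'
#' @param m an `omics_matrix` or plain matrix.
#' @return The per-gene z-scored matrix.
#' @export
zscore_standardize <- function(m) {
  v <- if (inherits(m, "omics_matrix")) observed_values(m) else m
  mu <- rowMeans(v, na.rm = TRUE)
  sd <- apply(v, 1, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd == 0] <- 1
  (v - mu) / sd
}

# cosine of sample s (group k) to each displayed gene's assigned reference,
# substituting the sample's value into the group-k slot of the gene's
# cross-group mean vector, averaged over genes
sample_avg_cosine <- function(proj_means, proj, grp, g, scores) {
  K <- length(g$groups)
  genes <- rownames(proj_means)
  dirs <- scores$direction[match(genes, scores$gene_id)]
  kass <- match(scores$assigned_group[match(genes, scores$gene_id)], g$groups)
  refs_sg <- signature_references(K, "SG")
  refs_dsg <- signature_references(K, "DSG")
  out <- numeric(ncol(proj))
  names(out) <- colnames(proj)
  kcol <- match(grp, g$groups)
  for (s in seq_along(out)) {
    vecs <- proj_means
    val <- proj[genes, s]
    ok <- !is.na(val)
    vecs[ok, kcol[s]] <- val[ok]
    ref_mat <- matrix(0, length(genes), K)
    use_sg <- dirs == "SG"
    ref_mat[use_sg, ] <- refs_sg[kass[use_sg], , drop = FALSE]
    ref_mat[!use_sg, ] <- refs_dsg[kass[!use_sg], , drop = FALSE]
    num <- rowSums(vecs * ref_mat)
    den <- sqrt(rowSums(vecs^2)) * sqrt(rowSums(ref_mat^2))
    cosv <- ifelse(den > 0, num / den, 0)
    out[s] <- mean(cosv, na.rm = TRUE)
  }
  out
}

#' Build the unified heatmap layout
#'
#' Combines simplex projection, display standardization and cosine-based
#' ordering. Rows are grouped by assigned group (label order) and sorted by
#' score descending (ties by gene id); columns are grouped by sample group
#' and sorted within group by the sample's gene-averaged cosine to the
#' assigned references (the sample's own value substituted into its
#' group's slot of each gene's mean vector). Genes absent from the score
#' table are excluded with a warning.
#'
#' @param m an `omics_matrix` (linear space, or log2 converted via `pseudo`).
#' @param g a [group_labels()] object.
#' @param scores a `signature_scores` table covering the displayed genes.
#' @param floor display clamp, see [display_standardize()].
#' @param pseudo pseudo-count for log2 inputs.
#' @return A `heatmap_layout` list: `display`, `projected`, `row_order`,
#'   `col_order`, `group_boundaries`, `floor`.
#' @export
build_layout <- function(m, g, scores, floor = NULL, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), inherits(scores, "signature_scores"))
  proj <- simplex_project(m, g, pseudo = pseudo)
  in_scores <- rownames(proj) %in% scores$gene_id
  if (!all(in_scores)) {
    warning(sum(!in_scores), " gene(s) without scores excluded from layout")
    pm <- attr(proj, "group_means")[in_scores, , drop = FALSE]
    proj <- proj[in_scores, , drop = FALSE]
    attr(proj, "group_means") <- pm
  }
  disp <- display_standardize(proj, g, floor = floor)
  idx <- match(rownames(proj), scores$gene_id)
  kass <- match(scores$assigned_group[idx], g$groups)
  row_order <- rownames(proj)[order(kass, -scores$score[idx],
                                    rownames(proj))]
  grp <- g$assignment[colnames(proj)]
  sc <- sample_avg_cosine(attr(proj, "group_means"), proj, grp, g, scores)
  col_order <- colnames(proj)[order(match(grp, g$groups), -sc,
                                    colnames(proj))]
  grp_sorted <- grp[col_order]
  bounds <- cumsum(table(factor(grp_sorted, levels = g$groups)))
  structure(list(display = disp[row_order, col_order, drop = FALSE],
                 projected = proj[row_order, col_order, drop = FALSE],
                 row_order = row_order, col_order = col_order,
                 group_boundaries = bounds,
                 floor = attr(disp, "floor")),
            class = "heatmap_layout")
}

#' Export a heatmap layout to files
#'
#' Writes `<prefix>.display.tsv` (the standardized matrix in layout
#' order), `<prefix>.roworder.txt`, `<prefix>.colorder.txt`, and
#' optionally `<prefix>.png` with a symmetric diverging colour map.
#'
#' @param layout a `heatmap_layout` from [build_layout()].
#' @param prefix output path prefix.
#' @param png if `TRUE`, also render a raster image.
#' @return Invisibly, the character vector of files written.
#' @export
export_layout <- function(layout, prefix, png = FALSE) {
  stopifnot(inherits(layout, "heatmap_layout"))
  files <- character(0)
  p <- paste0(prefix, ".display.tsv")
  df <- data.frame(gene_id = rownames(layout$display), layout$display,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  p <- paste0(prefix, ".roworder.txt")
  writeLines(layout$row_order, p); files <- c(files, p)
  p <- paste0(prefix, ".colorder.txt")
  writeLines(layout$col_order, p); files <- c(files, p)
  if (png) {
    p <- paste0(prefix, ".png")
    lim <- max(abs(layout$display), na.rm = TRUE)
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
    grDevices::png(p, width = 800, height = 800)
    graphics::image(t(layout$display[rev(seq_len(nrow(layout$display))), ,
                                     drop = FALSE]),
                    col = pal, zlim = c(-lim, lim), axes = FALSE,
                    main = "uniHM display")
    grDevices::dev.off()
    files <- c(files, p)
  }
  invisible(files)
}
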