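#' Quantify a compound against an internal standard
#'
#' Semi-quantification of a GC-MS peak by the internal-standard ratio method:
#' the target concentration is the ratio of the target peak area to the
#' internal-standard peak area, scaled by the spiked internal-standard mass and
#' divided by the sample mass.
#'
#' @param target_area Peak area of the target compound (arbitrary units,
#'   non-negative).
#' @param is_area Peak area of the internal standard (same units, > 0).
#' @param is_mass_ug Mass of internal standard spiked into the sample, in
#'   micrograms. Default 1.5 (15 uL of a 100 ppm ethyl decanoate solution).
#' @param sample_mass_g Sample mass in grams (> 0).
#' @return Concentration of the target in ng/g sample.
#' @examples
#' quantify_internal_standard(1000, 1000, 1.5, 5) # 300 ng/g
#' @export
quantify_internal_standard <- function(target_area, is_area,
                                       is_mass_ug = 1.5, sample_mass_g = 5) {
  stopifnot(is.numeric(target_area), is.numeric(is_area),
            is.numeric(is_mass_ug), is.numeric(sample_mass_g))
  if (any(target_area < 0)) stop("target_area must be non-negative")
  if (any(is_area <= 0)) stop("internal-standard peak area must be > 0 (division by zero)")
  if (any(sample_mass_g <= 0)) stop("sample mass must be > 0 (division by zero)")
  if (any(is_mass_ug <= 0)) stop("internal-standard mass must be > 0")
  # ug/g -> ng/g: x1000
  (target_area / is_area) * is_mass_ug / sample_mass_g * 1000
}

#' Sum mean concentrations of a compound class for one genotype
#'
#' Per-compound mean concentrations (over replicates) are summed within a
#' compound class (e.g. GLV, monoterpene, sesquiterpene), reproducing the
#' "Sum" rows of a volatile content table.
#'
#' @param table A volatile table data frame with columns `compound`, `class`,
#'   `genotype` and `concentration` (replicate-level) or `mean` (already
#'   averaged).
#' @param class Compound class to sum.
#' @param genotype Genotype whose concentrations are summed.
#' @return Sum of per-compound mean concentrations (ng/g).
#' @export
class_sum <- function(table, class, genotype) {
  stopifnot(is.data.frame(table), all(c("compound", "class", "genotype") %in% names(table)))
  value_col <- if ("concentration" %in% names(table)) "concentration" else "mean"
  if (!value_col %in% names(table))
    stop("table must have a 'concentration' or 'mean' column")
  rows <- table[table$class == class & table$genotype == genotype, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning(sprintf("no compounds of class '%s' for genotype '%s'; sum is 0",
                    class, genotype))
    return(0)
  }
  per_compound <- tapply(rows[[value_col]], rows$compound, mean)
  sum(per_compound)
}

#' Mid-parent heterosis value (MPV)
#'
#' MPV (%) = (F1 - MP) / MP * 100, where MP = (parent1 + parent2) / 2 is the
#' mid-parent trait value. Positive values mean the hybrid exceeds the
#' parental average.
#'
#' @param f1 Hybrid (F1) trait value.
#' @param p1,p2 Parental trait values.
#' @return Heterosis in percent.
#' @examples
#' mid_parent_heterosis(432.93, 400.67, 284.18) # 26.4
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  if (any(mp == 0)) stop("mid-parent value is zero; MPV undefined")
  (f1 - mp) / mp * 100
}

#' Over-high-parent heterosis value (OPV / HPV)
#'
#' OPV (%) = (F1 - HP) / HP * 100, where HP = max(parent1, parent2) is the
#' better-parent trait value. Positive values mean the hybrid exceeds its
#' better parent.
#'
#' @inheritParams mid_parent_heterosis
#' @return Heterosis in percent.
#' @examples
#' over_high_parent_heterosis(1500.79, 766.43, 916.7) # 63.7
#' @export
over_high_parent_heterosis <- function(f1, p1, p2) {
  hp <- pmax(p1, p2)
  if (any(hp == 0)) stop("high-parent value is zero; OPV undefined")
  (f1 - hp) / hp * 100
}

#' Heterosis indices for a trait
#'
#' Convenience wrapper returning the F1 value, mid-parent value, high-parent
#' value, MPV and OPV for one trait.
#'
#' @inheritParams mid_parent_heterosis
#' @param trait Optional trait label.
#' @return A one-row data frame with columns `trait`, `F1`, `MP`, `HP`,
#'   `MPV`, `OPV`.
#' @export
heterosis <- function(f1, p1, p2, trait = NA_character_) {
  data.frame(trait = trait, F1 = f1, MP = (p1 + p2) / 2, HP = pmax(p1, p2),
             MPV = mid_parent_heterosis(f1, p1, p2),
             OPV = over_high_parent_heterosis(f1, p1, p2),
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise Welch t-tests
#'
#' Groups are compared with pairwise two-sided Welch t-tests; letters are
#' assigned with the insert-and-absorb algorithm so that two groups share a
#' letter if and only if they are not significantly different at `alpha`.
#' Letters are assigned scanning groups in order of decreasing mean.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @param alpha Significance level for the pairwise tests (default 0.05).
#' @param bonferroni If TRUE, Bonferroni-adjust the pairwise p-values before
#'   thresholding. Default FALSE (raw p-values).
#' @return Named character vector of letter strings, one per group.
#' @examples
#' letter_groups(list(a = c(100, 104, 96), b = c(1, 1.1, 0.9)))
#' @export
letter_groups <- function(groups, alpha = 0.05, bonferroni = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2))
    stop(sprintf("group '%s' has < 2 replicates", names(groups)[sizes < 2][1]))

  k <- length(groups)
  pmat <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- groups[[i]]; y <- groups[[j]]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        p <- if (mean(x) == mean(y)) 1 else 0
      } else {
        p <- stats::t.test(x, y, var.equal = FALSE)$p.value
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  if (bonferroni) pmat <- pmin(pmat * choose(k, 2), 1)
  cld_insert_absorb(pmat < alpha, order(-vapply(groups, mean, 1)))
}

# Insert-and-absorb compact letter display on a logical significance matrix.
# `signif` is k x k, TRUE where the pair differs; `scan_order` gives the group
# scan sequence (here: decreasing mean). Returns letter strings in input order.
cld_insert_absorb <- function(signif, scan_order = seq_len(nrow(signif))) {
  k <- nrow(signif)
  letters_sets <- list(scan_order) # each element: vector of group indices sharing a letter
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      i <- scan_order[a]; j <- scan_order[b]
      if (!signif[i, j]) next
      for (s in seq_along(letters_sets)) {
        set <- letters_sets[[s]]
        if (i %in% set && j %in% set) {
          # duplicate the letter, dropping one offender from each copy
          letters_sets[[s]] <- setdiff(set, j)
          letters_sets[[length(letters_sets) + 1]] <- setdiff(set, i)
        }
      }
      # absorb: drop sets that are subsets of another set
      keep <- rep(TRUE, length(letters_sets))
      for (s in seq_along(letters_sets)) {
        for (t in seq_along(letters_sets)) {
          if (s != t && keep[t] &&
              all(letters_sets[[s]] %in% letters_sets[[t]]) &&
              (length(letters_sets[[s]]) < length(letters_sets[[t]]) || s > t)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      letters_sets <- letters_sets[keep]
    }
  }
  # order letters by first appearance along the scan order, then label a, b, c...
  first_pos <- vapply(letters_sets, function(s) min(match(s, scan_order)), 1)
  letters_sets <- letters_sets[order(first_pos)]
  out <- character(k)
  for (s in seq_along(letters_sets)) {
    lab <- letters[(s - 1) %% 26 + 1]
    if (s > 26) lab <- paste0(lab, (s - 1) %/% 26)
    for (g in letters_sets[[s]]) out[g] <- paste0(out[g], lab)
  }
  names(out) <- rownames(signif)
  out
}

#' Summarise a replicate-level volatile table
#'
#' Computes per-compound (and per-class "Sum") means, standard deviations and
#' compact letter displays across genotypes, mirroring the layout of a
#' volatile content table.
#'
#' @param table Volatile table data frame with columns `compound`, `class`,
#'   `genotype`, `replicate`, `concentration`.
#' @param alpha Significance level for the letter display.
#' @return Data frame with columns `compound`, `class`, `genotype`, `mean`,
#'   `sd`, `letter`; class sums appear as compound `Sum (<class>)`.
#' @export
summarize_volatiles <- function(table, alpha = 0.05) {
  stopifnot(all(c("compound", "class", "genotype", "replicate", "concentration")
                %in% names(table)))
  rows <- list()
  for (cl in unique(table$class)) {
    sub <- table[table$class == cl, , drop = FALSE]
    genos <- unique(sub$genotype)
    for (cmp in unique(sub$compound)) {
      cs <- sub[sub$compound == cmp, , drop = FALSE]
      grps <- split(cs$concentration, cs$genotype)[genos]
      lets <- tryCatch(letter_groups(grps, alpha), error = function(e) {
        stats::setNames(rep(NA_character_, length(grps)), names(grps))
      })
      rows[[length(rows) + 1]] <- data.frame(
        compound = cmp, class = cl, genotype = genos,
        mean = vapply(grps, mean, 1), sd = vapply(grps, stats::sd, 1),
        letter = lets[genos], stringsAsFactors = FALSE, row.names = NULL)
    }
    # class sums: per-replicate sums over compounds, then mean/sd/letters
    sums <- stats::aggregate(concentration ~ genotype + replicate, data = sub, FUN = sum)
    grps <- split(sums$concentration, sums$genotype)[genos]
    lets <- tryCatch(letter_groups(grps, alpha), error = function(e) {
      stats::setNames(rep(NA_character_, length(grps)), names(grps))
    })
    rows[[length(rows) + 1]] <- data.frame(
      compound = sprintf("Sum (%s)", cl), class = cl, genotype = genos,
      mean = vapply(grps, mean, 1), sd = vapply(grps, stats::sd, 1),
      letter = lets[genos], stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Heterosis table for class sums of a volatile table
#'
#' For each compound class and each hybrid, computes MPV and OPV of the class
#' sum relative to the two parents.
#'
#' @param class_sums Data frame with columns `class`, `genotype`, `value`
#'   (one class-sum per genotype), or a replicate-level volatile table (then
#'   sums are computed with [class_sum()]).
#' @param hybrids Character vector of the two hybrid genotype names.
#' @param parents Character vector of the two parent genotype names.
#' @return Data frame with columns `hybrid`, `class`, `F1`, `MP`, `HP`,
#'   `MPV`, `OPV`.
#' @export
volatile_heterosis_table <- function(class_sums, hybrids, parents) {
  stopifnot(length(hybrids) == 2, length(parents) == 2)
  if (!all(c("class", "genotype", "value") %in% names(class_sums))) {
    stopifnot(all(c("compound", "class", "genotype") %in% names(class_sums)))
    grid <- expand.grid(class = unique(class_sums$class),
                        genotype = unique(class_sums$genotype),
                        stringsAsFactors = FALSE)
    grid$value <- mapply(function(cl, g) class_sum(class_sums, cl, g),
                         grid$class, grid$genotype)
    class_sums <- grid
  }
  get <- function(cl, g) {
    v <- class_sums$value[class_sums$class == cl & class_sums$genotype == g]
    if (length(v) != 1) stop(sprintf("need exactly one value for class '%s', genotype '%s'", cl, g))
    v
  }
  out <- list()
  for (h in hybrids) {
    for (cl in unique(class_sums$class)) {
      p1 <- get(cl, parents[1]); p2 <- get(cl, parents[2]); f1 <- get(cl, h)
      out[[length(out) + 1]] <- data.frame(
        hybrid = h, class = cl, F1 = f1, MP = (p1 + p2) / 2, HP = max(p1, p2),
        MPV = mid_parent_heterosis(f1, p1, p2),
        OPV = over_high_parent_heterosis(f1, p1, p2),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
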