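## Vector-control quantitative analysis (VCQA): efficiency-corrected qPCR
## relative quantification of plastid, mitochondrial and nuclear DNA in a
## mixed sample, and dataset-size prediction for organelle assembly.

#' Construct a qPCR measurement
#'
#' One amplicon's amplification efficiency and its paired cycle-threshold
#' values: CT measured on the control vector (which carries one marker gene
#' per genome compartment at equimolar copy number) and CT measured on the
#' DNA sample.
#'
#' @param gene_id marker gene name (e.g. `"rpoB"`, `"ccmB"`, `"actin"`).
#' @param role one of `"plastid"`, `"mitochondrial"`, `"nuclear"`.
#' @param efficiency amplification efficiency E in (0, 1.5]; E = 1 means
#'   perfect doubling per cycle, so the amplification base is 1 + E.
#' @param ct_control CT (cycles) on the control vector; must be positive.
#' @param ct_sample CT (cycles) on the DNA sample; must be positive.
#' @return an object of class `qpcr_measurement`.
#' @examples
#' qpcr_measurement("actin", "nuclear", 1.124, 17.79, 23.70)
#' @export
qpcr_measurement <- function(gene_id, role = c("plastid", "mitochondrial", "nuclear"),
                             efficiency, ct_control, ct_sample) {
  role <- match.arg(role)
  if (!is.numeric(efficiency) || length(efficiency) != 1L || is.na(efficiency) ||
      efficiency <= 0 || efficiency > 1.5) {
    stop("invalid measurement: efficiency must be in (0, 1.5], got ", efficiency)
  }
  if (ct_control <= 0 || ct_sample <= 0) {
    stop("invalid measurement: CT values must be positive")
  }
  structure(
    list(gene_id = gene_id, role = role, efficiency = efficiency,
         ct_control = ct_control, ct_sample = ct_sample),
    class = "qpcr_measurement"
  )
}

#' @export
print.qpcr_measurement <- function(x, ...) {
  cat(sprintf("<qpcr_measurement> %s (%s): E=%.3f CT(control)=%.2f CT(sample)=%.2f dCT=%.2f\n",
              x$gene_id, x$role, x$efficiency, x$ct_control, x$ct_sample,
              x$ct_control - x$ct_sample))
  invisible(x)
}

#' Efficiency-corrected relative quantity
#'
#' Computes `(1 + E) ^ (CT_control - CT_sample)`: the quantity of the
#' amplicon's template in the sample relative to the equimolar control
#' vector, corrected for the amplicon's own amplification efficiency.
#' Rounding to 4 decimal places matches the precision at which such tables
#' are customarily printed, and is the precision at which the downstream
#' integer copy folds are defined (see [copy_fold()]).
#'
#' @param m a [qpcr_measurement()].
#' @param round_digits decimal places for the returned value; `Inf` (or
#'   `NULL`) skips rounding.
#' @return positive numeric scalar.
#' @examples
#' relative_quantity(qpcr_measurement("actin", "nuclear", 1.124, 17.79, 23.70))
#' @export
relative_quantity <- function(m, round_digits = 4L) {
  stopifnot(inherits(m, "qpcr_measurement"))
  if (m$efficiency <= 0) stop("invalid measurement: non-positive efficiency")
  q <- (1 + m$efficiency)^(m$ct_control - m$ct_sample)
  if (is.null(round_digits) || !is.finite(round_digits)) return(q)
  round_half_away(q, round_digits)
}

#' Organelle/nuclear copy fold
#'
#' Ratio of an organelle amplicon's relative quantity to the nuclear
#' amplicon's, rounded half-away-from-zero to the nearest integer. By
#' default both relative quantities are first rounded to 4 decimals, the
#' precision at which they are printed and at which the published integer
#' folds are reproducible; set `exact = TRUE` to ratio the unrounded
#' quantities (for scientific use the unrounded ratio is the better
#' estimator, but its integer rounding need not match a printed table).
#'
#' @param organelle a [qpcr_measurement()] with role plastid or mitochondrial.
#' @param nuclear a [qpcr_measurement()] with role nuclear.
#' @param exact skip the 4-decimal intermediate rounding.
#' @return positive integer copy fold.
#' @examples
#' nuc <- qpcr_measurement("actin", "nuclear", 1.124, 17.79, 23.70)
#' mit <- qpcr_measurement("ccmB", "mitochondrial", 1.060, 17.64, 17.87)
#' copy_fold(mit, nuc)  # 72
#' @export
copy_fold <- function(organelle, nuclear, exact = FALSE) {
  stopifnot(inherits(organelle, "qpcr_measurement"), inherits(nuclear, "qpcr_measurement"))
  if (!identical(organelle$gene_id, nuclear$gene_id)) {
    if (nuclear$role != "nuclear") stop("reference measurement must have role 'nuclear'")
    if (organelle$role == "nuclear") stop("organelle measurement must not have role 'nuclear'")
  }
  digits <- if (exact) NULL else 4L
  qo <- relative_quantity(organelle, digits)
  qn <- relative_quantity(nuclear, digits)
  if (qn == 0) stop("division error: nuclear relative quantity is zero")
  as.integer(round_half_away(qo / qn))
}

#' Unrounded copy-fold ratio
#'
#' The raw ratio of relative quantities, with no intermediate or final
#' rounding. Useful for propagating uncertainty and for the reciprocal
#' identity `copy_fold_ratio(a, b) * copy_fold_ratio(b, a) == 1`.
#'
#' @inheritParams copy_fold
#' @return positive numeric scalar.
#' @export
copy_fold_ratio <- function(organelle, nuclear) {
  qo <- relative_quantity(organelle, NULL)
  qn <- relative_quantity(nuclear, NULL)
  if (qn == 0) stop("division error: nuclear relative quantity is zero")
  qo / qn
}

#' Dataset size needed for a target organelle depth
#'
#' With an organelle present at `copy_fold` copies per nuclear genome copy,
#' sequencing the sample to `target_depth` layers over the organelle
#' requires `nuclear_genome_size * target_depth / copy_fold` bases (the
#' nuclear genome is then covered `target_depth / copy_fold` layers).
#'
#' @param nuclear_genome_size nuclear genome size in bases.
#' @param copy_fold organelle/nuclear copy fold (positive).
#' @param target_depth desired organelle sequencing depth in layers; 50 is
#'   a customary floor for a clean de novo assembly.
#' @return required dataset size in bases.
#' @examples
#' required_bases(1.2e9, 72, 50)  # < 1.2e9, so 1.2 Gb suffices
#' @export
required_bases <- function(nuclear_genome_size, copy_fold, target_depth = 50) {
  stopifnot(nuclear_genome_size > 0, copy_fold > 0, target_depth > 0)
  nuclear_genome_size * target_depth / copy_fold
}

#' Read a qPCR table from CSV
#'
#' Expects a UTF-8 CSV with header `gene,role,efficiency,ct_control,ct_sample`
#' and decimal points.
#'
#' @param path CSV file path.
#' @return named list of [qpcr_measurement()] objects, keyed by gene.
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("gene", "role", "efficiency", "ct_control", "ct_sample")
  if (!all(need %in% names(tab))) {
    stop("qPCR CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    qpcr_measurement(tab$gene[i], tab$role[i], tab$efficiency[i],
                     tab$ct_control[i], tab$ct_sample[i])
  })
  names(out) <- tab$gene
  out
}

#' Summarise sample purity and dataset sufficiency
#'
#' Computes every amplicon's relative quantity, the plastid/nuclear and
#' mitochondrial/nuclear copy folds, and (optionally) the dataset size at
#' which each organelle reaches a target assembly depth.
#'
#' @param measurements list of [qpcr_measurement()] (exactly one with role
#'   nuclear; at least one organelle).
#' @param nuclear_genome_size optional nuclear genome size in bases.
#' @param target_depth target organelle depth in layers (default 50).
#' @param exact passed to [copy_fold()].
#' @return an object of class `purity_report`: list with `rel_quantity`
#'   (named numeric), `copy_fold_pt`, `copy_fold_mt` (integers or NA), and
#'   a `dataset` data.frame when `nuclear_genome_size` is given.
#' @export
purity_report <- function(measurements, nuclear_genome_size = NULL,
                          target_depth = 50, exact = FALSE) {
  roles <- vapply(measurements, `[[`, "", "role")
  if (sum(roles == "nuclear") != 1L) {
    stop("purity_report needs exactly one nuclear measurement")
  }
  nuc <- measurements[[which(roles == "nuclear")]]
  relq <- vapply(measurements, relative_quantity, 0, round_digits = 4L)
  names(relq) <- vapply(measurements, `[[`, "", "gene_id")
  fold_of <- function(role) {
    i <- which(roles == role)
    if (length(i) == 0L) return(NA_integer_)
    copy_fold(measurements[[i[1L]]], nuc, exact = exact)
  }
  rep <- list(
    rel_quantity = relq,
    copy_fold_pt = fold_of("plastid"),
    copy_fold_mt = fold_of("mitochondrial")
  )
  if (!is.null(nuclear_genome_size)) {
    folds <- c(plastid = rep$copy_fold_pt, mitochondrial = rep$copy_fold_mt)
    folds <- folds[!is.na(folds)]
    rep$dataset <- data.frame(
      compartment = names(folds),
      copy_fold = as.integer(folds),
      target_depth = target_depth,
      required_bases = vapply(folds, function(f)
        required_bases(nuclear_genome_size, f, target_depth), 0),
      row.names = NULL
    )
  }
  class(rep) <- "purity_report"
  rep
}

#' @export
print.purity_report <- function(x, ...) {
  cat("gene\trel_quantity\n")
  for (g in names(x$rel_quantity)) cat(sprintf("%s\t%.4f\n", g, x$rel_quantity[[g]]))
  cat(sprintf("copy_fold_pt\t%s\n", x$copy_fold_pt))
  cat(sprintf("copy_fold_mt\t%s\n", x$copy_fold_mt))
  if (!is.null(x$dataset)) {
    cat("compartment\tcopy_fold\ttarget_depth\trequired_bases\n")
    for (i in seq_len(nrow(x$dataset))) {
      cat(sprintf("%s\t%d\t%g\t%.0f\n", x$dataset$compartment[i],
                  x$dataset$copy_fold[i], x$dataset$target_depth[i],
                  x$dataset$required_bases[i]))
    }
  }
  invisible(x)
}
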