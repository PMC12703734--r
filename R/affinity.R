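#' Gas constant, kcal/(mol K)
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Convert an experimental affinity to a binding free energy
#'
#' \deqn{\Delta G \approx R T \ln K_D} with \eqn{R} = 1.9872e-3 kcal/(mol K).
#' Inhibition constants and IC50 values are treated as dissociation-constant
#' surrogates, the usual benchmark convention. A record can instead carry
#' \code{dg} directly, which passes through unchanged.
#'
#' @param affinity dissociation-type constant, mol/L (exclusive with dg).
#' @param dg free energy, kcal/mol (passthrough).
#' @param temperature absolute temperature, K.
#' @param kind one of "KD", "Ki", "IC50" (informational).
#' @return binding free energy, kcal/mol.
#' @export
affinity_to_dg <- function(affinity = NULL, dg = NULL, temperature = 298.15,
                           kind = c("KD", "Ki", "IC50")) {
  kind <- match.arg(kind)
  if (is.null(affinity) == is.null(dg))
    stop("exactly one of 'affinity' and 'dg' must be given")
  if (!is.null(dg)) return(dg)
  if (any(affinity <= 0)) stop("affinity must be positive (mol/L)")
  GAS_CONSTANT_KCAL * temperature * log(affinity)
}

#' Read a delimited affinity table
#'
#' Expected columns: \code{pdb_id}, \code{value}, \code{kind} (KD/Ki/IC50 in
#' mol/L, or DG in kcal/mol), optional \code{temperature} (K). The packaged
#' benchmark table of 20 protein-protein complexes with experimental
#' binding free energies ships at
#' \code{system.file("extdata", "ppi_benchmark_affinities.tsv",
#' package = "mnmgbsa")}.
#'
#' @param path file path.
#' @return data.frame with a computed \code{dg} column, kcal/mol.
#' @export
read_affinity_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pdb_id", "value", "kind")
  if (!all(need %in% names(tab)))
    stop("affinity table needs columns: ", paste(need, collapse = ", "))
  if (is.null(tab$temperature)) tab$temperature <- 298.15
  kind <- toupper(tab$kind)
  bad <- setdiff(unique(kind), c("DG", "KD", "KI", "IC50"))
  if (length(bad)) stop("unknown affinity kind(s): ", paste(bad, collapse = ", "))
  tab$dg <- ifelse(kind == "DG", tab$value,
                   GAS_CONSTANT_KCAL * tab$temperature *
                     log(ifelse(kind == "DG", 1, tab$value)))
  if (any(kind != "DG" & tab$value <= 0))
    stop("affinity constants must be positive (mol/L)")
  tab
}

#' Correlation between predicted and experimental binding free energies
#'
#' Least-squares line and squared Pearson correlation (r^2, equivalently
#' the unadjusted R^2 of the univariate fit). Complexes listed in
#' \code{exclude} are dropped before fitting and recorded, supporting
#' leave-one-out outlier analyses.
#'
#' @param experimental,predicted paired numeric vectors, kcal/mol.
#' @param ids complex identifiers (default index).
#' @param exclude ids to leave out.
#' @return object of class \code{correlation_report}: n, r2, slope,
#'   intercept, residuals (per id), excluded.
#' @export
correlation_report <- function(experimental, predicted,
                               ids = seq_along(experimental),
                               exclude = character(0)) {
  if (length(experimental) != length(predicted))
    stop("series lengths differ")
  keep <- !(as.character(ids) %in% as.character(exclude))
  x <- experimental[keep]; y <- predicted[keep]
  if (length(x) < 3L) stop("need at least 3 complexes after exclusions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  fit <- stats::lm(y ~ x)
  r2 <- stats::cor(x, y)^2
  structure(list(n = length(x), r2 = r2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = stats::setNames(stats::resid(fit),
                                             as.character(ids[keep])),
                 excluded = as.character(exclude)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation report: n = %d, r^2 = %.2f, fit y = %.3f x %+.3f\n",
              x$n, x$r2, x$slope, x$intercept))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Relative binding free energy (ddG) correlation
#'
#' Forms \eqn{\Delta\Delta G_{ij} = \Delta G_i - \Delta G_j} for complex
#' pairs in both series and reports their squared correlation. Constant
#' offsets common to a series cancel by construction. Pairing is either
#' all unordered pairs (default) or differences to a reference complex.
#'
#' @inheritParams correlation_report
#' @param pairing "all" (n(n-1)/2 unordered pairs) or "reference".
#' @param reference reference id when \code{pairing = "reference"}.
#' @return a \code{correlation_report} over the pair differences.
#' @export
ddg_report <- function(experimental, predicted,
                       ids = seq_along(experimental),
                       pairing = c("all", "reference"), reference = NULL,
                       exclude = character(0)) {
  pairing <- match.arg(pairing)
  keep <- !(as.character(ids) %in% as.character(exclude))
  x <- experimental[keep]; y <- predicted[keep]; id <- as.character(ids[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complexes after exclusions")
  if (pairing == "all") {
    cmb <- utils::combn(n, 2)
    dx <- x[cmb[1, ]] - x[cmb[2, ]]
    dy <- y[cmb[1, ]] - y[cmb[2, ]]
    pid <- paste(id[cmb[1, ]], id[cmb[2, ]], sep = "-")
  } else {
    if (is.null(reference) || !(reference %in% id))
      stop("reference id required and must be present")
    r <- match(reference, id)
    dx <- (x - x[r])[-r]; dy <- (y - y[r])[-r]
    pid <- paste(id[-r], reference, sep = "-")
  }
  correlation_report(dx, dy, ids = pid)
}
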