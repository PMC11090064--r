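#' Amino-acid residue property table
#'
#' Per-residue constants for the 20 standard amino acids: dehydrated
#' residue mass (amino-acid mass minus one water), consensus residue
#' volume, the literature specific refractive increment \code{dndc}
#' (dilute-limit Wiener value at the sodium-D line in water), the residue
#' PSV \code{theta} derived from the volume, and the refraction per gram
#' \code{R} obtained by inverting the dilute-limit Wiener relation at
#' \code{n1} so that the tabulated \code{dndc} values are reproduced
#' exactly. The bundled values are literature stand-ins (residue
#' refractive increments following Zhao and co-workers; consensus residue
#' volumes) and can be swapped by pointing \code{path} at a CSV with
#' columns \code{aa, residue_mass, volume_A3, dndc}.
#'
#' @param path CSV file; default is the bundled table
#' @param n1 solvent refractive index used to derive \code{R}
#' @return data.frame with columns \code{aa, residue_mass, volume_A3,
#'   dndc, theta, R}
#' @export
residue_table <- function(path = NULL, n1 = 1.3330) {
  if (is.null(path))
    path <- system.file("extdata", "residues.csv", package = "ridens")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("aa", "residue_mass", "volume_A3", "dndc")
  if (!all(need %in% names(tab))) stop("residue table must have columns: ",
                                       paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$aa))
    stop("residue table must list the 20 standard amino acids once each")
  if (any(tab$residue_mass <= 0) || any(tab$volume_A3 <= 0) || any(tab$dndc <= 0))
    stop("residue constants must be positive")
  # Avogadro constant x 1e-24 converts A^3/residue to mL/mol
  tab$theta <- tab$volume_A3 * 0.6022141 / tab$residue_mass
  if (any(tab$theta < 0.4 | tab$theta > 1.2))
    stop("residue PSV outside the (0.4, 1.2) mL/g sanity band")
  # invert alpha_W = (3/2) theta n1 (n2^2 - n1^2)/(n2^2 + 2 n1^2) for n2,
  # then R via Lorentz-Lorenz at rho = 1/theta
  k <- 2 * tab$dndc / (3 * tab$theta * n1)
  if (any(k >= 1)) stop("residue dndc too large for the Wiener inversion")
  n2sq <- n1^2 * (1 + 2 * k) / (1 - k)
  tab$R <- tab$theta * (n2sq - 1) / (n2sq + 2)
  rownames(tab) <- tab$aa
  tab
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around \code{Biostrings} FASTA input (plain or gzipped).
#' Sequences are uppercased and trailing/embedded \code{*} stop characters
#' are removed.
#'
#' @param path FASTA file
#' @return data.frame with columns \code{id} and \code{sequence}, in file
#'   order; zero rows for an empty file
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  data.frame(id = names(ss), sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Refraction per gram and PSV of a protein from its sequence
#'
#' Molar-mass-weighted residue averaging: with residue counts \eqn{c_i} and
#' dehydrated residue masses \eqn{M_i}, the weights are \eqn{w_i = c_i M_i /
#' \sum_j c_j M_j} and
#' \deqn{R_p = \sum_i w_i R_i, \qquad \theta_p = \sum_i w_i \theta_i.}
#' Non-standard letters (B, J, O, U, X, Z and gaps) are skipped with a
#' warning and excluded from the weight normalisation. No terminal-water
#' correction is applied (negligible for proteome-scale chains).
#'
#' @param sequence amino-acid sequence string
#' @param table a [residue_table()]
#' @return list with \code{R_p} and \code{theta_p} (mL/g) and the number of
#'   scored residues \code{n_scored}
#' @export
protein_props <- function(sequence, table = residue_table()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars <- chars[chars != "*"]
  known <- chars %in% table$aa
  if (any(!known))
    warning(sprintf("skipping %d non-standard residue(s): %s",
                    sum(!known), paste(unique(chars[!known]), collapse = "")))
  chars <- chars[known]
  if (length(chars) == 0L) stop("sequence contains no scorable residues")
  cnt <- table(factor(chars, levels = table$aa))
  w <- as.numeric(cnt) * table$residue_mass
  w <- w / sum(w)
  list(R_p = sum(w * table$R), theta_p = sum(w * table$theta),
       n_scored = length(chars))
}

#' RI increment of a protein from its refraction per gram and PSV
#'
#' The pure-protein refractive index \eqn{n_p} follows from the
#' Lorentz-Lorenz relation at density \eqn{1/\theta_p}; the RI increment is
#' then either the Biot value \eqn{\theta_p (n_p - n_1)} or the
#' dilute-limit Wiener value (see [alpha_wiener_dilute()]). The Biot value
#' is systematically the larger of the two.
#'
#' @param R_p refraction per gram, mL/g
#' @param theta_p PSV, mL/g
#' @param solvent a [solvent()] object
#' @param rule \code{"biot"} or \code{"wiener_dilute"}
#' @return RI increment, mL/g
#' @export
protein_alpha <- function(R_p, theta_p, solvent = ridens::solvent(),
                          rule = c("biot", "wiener_dilute")) {
  rule <- match.arg(rule)
  n_p <- ri_from_material(R_p, 1 / theta_p)
  switch(rule,
         biot = alpha_biot(theta_p, n_p, solvent$n1),
         wiener_dilute = alpha_wiener_dilute(R_p, theta_p, solvent$n1))
}

#' Per-protein properties for a set of sequences
#'
#' Applies [protein_props()] and [protein_alpha()] to every record,
#' returning one row per protein.
#'
#' @param records data.frame with columns \code{id, sequence} (e.g. from
#'   [read_fasta()])
#' @param table a [residue_table()]
#' @param solvent a [solvent()] object
#' @return data.frame with columns \code{id, length, R_p, theta_p,
#'   alpha_W, alpha_B}
#' @export
proteome_props <- function(records, table = residue_table(),
                           solvent = ridens::solvent()) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- protein_props(records$sequence[i], table)
    data.frame(id = records$id[i], length = p$n_scored,
               R_p = p$R_p, theta_p = p$theta_p,
               alpha_W = protein_alpha(p$R_p, p$theta_p, solvent, "wiener_dilute"),
               alpha_B = protein_alpha(p$R_p, p$theta_p, solvent, "biot"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ensemble statistics of (RI increment, PSV) pairs
#'
#' Univariate maximum-likelihood normal fits per axis (mean = sample mean,
#' SD = sample SD) plus the 68\%/95\% elliptical contour parameters of the
#' bivariate sample (principal axes of the sample covariance scaled by
#' chi-squared quantiles).
#'
#' @param props data.frame with an RI-increment column (\code{alpha_B} by
#'   default) and \code{theta_p}
#' @param alpha_col which RI-increment column to summarise
#' @return object of class \code{"ensemble_stats"}
#' @export
ensemble_stats <- function(props, alpha_col = "alpha_B") {
  stopifnot(is.data.frame(props), alpha_col %in% names(props),
            "theta_p" %in% names(props))
  if (nrow(props) < 2L) stop("need at least 2 records for ensemble statistics")
  a <- props[[alpha_col]]; th <- props$theta_p
  S <- stats::cov(cbind(a, th))
  ev <- eigen(S, symmetric = TRUE)
  ell <- lapply(c(`68` = stats::qchisq(0.68, 2), `95` = stats::qchisq(0.95, 2)),
                function(q) list(center = c(alpha = mean(a), theta = mean(th)),
                                 axes = sqrt(q * ev$values),
                                 rotation = ev$vectors))
  structure(list(n_proteins = nrow(props),
                 alpha = c(mean = mean(a), sd = stats::sd(a)),
                 theta = c(mean = mean(th), sd = stats::sd(th)),
                 ellipses = ell, alpha_col = alpha_col),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("Ensemble of %d proteins (%s):\n", x$n_proteins, x$alpha_col))
  cat(sprintf("  alpha: %.4f +/- %.4f mL/g\n", x$alpha["mean"], x$alpha["sd"]))
  cat(sprintf("  theta: %.4f +/- %.4f mL/g\n", x$theta["mean"], x$theta["sd"]))
  invisible(x)
}

#' Table-derived protein parameter sets
#'
#' Published mean/SD values of the Wiener and Biot RI increments and the
#' PSV for whole-proteome and tissue-specific protein ensembles
#' (human/zebrafish proteomes and larval zebrafish trunk tissue), bundled
#' as a CSV. These are transcriptions of published summary values, usable
#' as solute-component parameters without recomputing a proteome.
#'
#' @param set optional row to extract (e.g. \code{"zebrafish_trunk"}); if
#'   missing the whole table is returned
#' @return data.frame, or (for a single set) a list with \code{alpha}
#'   (Biot), \code{theta}, \code{dalpha}, \code{dtheta}, \code{alpha_W},
#'   \code{dalpha_W}, \code{name}
#' @export
protein_params <- function(set = NULL) {
  path <- system.file("extdata", "protein_params.csv", package = "ridens")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(set)) return(tab)
  row <- tab[tab$set == set, ]
  if (nrow(row) != 1L) stop("unknown protein parameter set: ", set)
  list(name = set, alpha = row$alpha_B, dalpha = row$dalpha_B,
       theta = row$theta, dtheta = row$dtheta,
       alpha_W = row$alpha_W, dalpha_W = row$dalpha_W)
}
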