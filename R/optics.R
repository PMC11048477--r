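#' Wavelength triple of the instrument
#'
#' The device illuminates with a multiwavelength LED; all estimators in the
#' package index their spectra by this strictly increasing triple.
#'
#' @param lambda1,lambda2,lambda3 wavelengths in nm; defaults 730, 800, 850
#' @return numeric vector of length 3, class `wavelength_triple`
#' @export
wavelength_triple <- function(lambda1 = 730, lambda2 = 800, lambda3 = 850) {
  w <- c(lambda1, lambda2, lambda3)
  abort_if(!is.numeric(w) || length(w) != 3 || anyNA(w),
           "wavelength_triple needs three numeric wavelengths")
  abort_if(any(w <= 0) || any(diff(w) <= 0),
           "wavelengths must be positive and strictly increasing")
  structure(as.numeric(w), class = "wavelength_triple")
}

#' Load an extinction-coefficient table
#'
#' Reads a CSV with columns `wavelength_nm`, `eps_hbo`, `eps_hb` (lines
#' starting with `#` are comments). Units are cm^-1 uM^-1 under the base-10
#' (decadic) convention: mu_a = eps_HbO * C_HbO + eps_Hb * C_Hb with
#' concentrations in uM gives mu_a in cm^-1. The packaged default table is
#' a standard compiled hemoglobin spectrum at 730/800/850 nm.
#'
#' @param path CSV path; `NULL` loads the packaged default table
#' @return tibble with class `extinction_table`
#' @export
extinction_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hemoglobin_extinction.csv",
                                package = "cwnirs", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo", "eps_hb")
  abort_if(!all(need %in% names(tab)),
           "extinction table must have columns %s", paste(need, collapse = ", "))
  tab <- tibble::as_tibble(tab[need])
  abort_if(nrow(tab) < 2, "extinction table needs at least two wavelengths")
  abort_if(anyDuplicated(tab$wavelength_nm) > 0, "duplicate wavelengths in extinction table")
  abort_if(any(tab$eps_hbo <= 0) || any(tab$eps_hb <= 0),
           "extinction coefficients must be positive")
  class(tab) <- c("extinction_table", class(tab))
  tab
}

# Extinction matrix E (n_wavelength x 2, columns HbO then Hb) for the
# requested wavelengths, in table order of the request.
extinction_matrix <- function(table, wavelengths) {
  i <- match(wavelengths, table$wavelength_nm)
  abort_if(anyNA(i), "extinction table has no entry for wavelength(s) %s",
           paste(wavelengths[is.na(i)], collapse = ", "))
  cbind(eps_hbo = table$eps_hbo[i], eps_hb = table$eps_hb[i])
}

#' Differential pathlength factors per wavelength
#'
#' @param dpf1,dpf2,dpf3 dimensionless DPF at each wavelength
#' @return numeric vector of length 3
#' @export
dpf_set <- function(dpf1, dpf2, dpf3) {
  d <- c(dpf1, dpf2, dpf3)
  abort_if(!is.numeric(d) || length(d) != 3 || anyNA(d) || any(d <= 0),
           "DPFs must be three positive numbers")
  structure(as.numeric(d), class = "dpf_set")
}

#' Equal DPF at all three wavelengths
#'
#' The breath-hold analysis assumes a wavelength-independent DPF. The
#' default 6.0 is a conventional adult-forehead value; the instrument's own
#' DPF is not published, so this is a configurable package default.
#'
#' @param value the common DPF (default 6)
#' @export
equal_dpf <- function(value = 6) dpf_set(value, value, value)

#' Probe geometry
#'
#' @param separations source-detector distances in cm (device default 3 and 4)
#' @param require_two require exactly two distinct separations (needed by SRS)
#' @export
geometry <- function(separations = c(3, 4), require_two = FALSE) {
  abort_if(!is.numeric(separations) || any(separations <= 0),
           "separations must be positive distances in cm")
  if (require_two)
    abort_if(length(unique(separations)) != 2,
             "SRS requires exactly two distinct separations")
  structure(as.numeric(separations), class = "nirs_geometry")
}

#' Chromophore concentration state
#'
#' Oxy- and deoxyhemoglobin concentrations with derived total hemoglobin
#' (THb = HbO + Hb) and tissue oxygen saturation
#' StO2 = 100 * HbO / (HbO + Hb) in percent. Vectorised: pass equal-length
#' concentration vectors for a time series of states.
#'
#' @param c_hbo,c_hb concentrations in uM
#' @return tibble with columns `c_hbo`, `c_hb`, `thb`, `sto2`
#' @export
chromophore_state <- function(c_hbo, c_hb) {
  abort_if(length(c_hbo) != length(c_hb), "c_hbo and c_hb must have equal length")
  abort_if(anyNA(c_hbo) || anyNA(c_hb), "concentrations must be non-missing")
  thb <- c_hbo + c_hb
  sto2 <- ifelse(thb == 0, NA_real_, 100 * c_hbo / thb)
  out <- tibble::tibble(c_hbo = as.numeric(c_hbo), c_hb = as.numeric(c_hb),
                        thb = thb, sto2 = sto2)
  class(out) <- c("chromophore_state", class(out))
  out
}

#' Absorption coefficient from a chromophore state
#'
#' Two-chromophore model: mu_a(lambda) = eps_HbO(lambda) * C_HbO +
#' eps_Hb(lambda) * C_Hb, in cm^-1 (base-10 convention).
#'
#' @param state a [chromophore_state()] (possibly many rows)
#' @param table an [extinction_table()]
#' @param wavelengths wavelengths to evaluate; default all in `table`
#' @return matrix (n_states x n_wavelengths) of mu_a, columns named by wavelength
#' @export
absorption_from_state <- function(state, table = extinction_table(),
                                  wavelengths = table$wavelength_nm) {
  abort_if(any(state$c_hbo < 0) || any(state$c_hb < 0),
           "concentrations must be non-negative")
  E <- extinction_matrix(table, wavelengths)
  mua <- cbind(state$c_hbo, state$c_hb) %*% t(E)
  colnames(mua) <- as.character(wavelengths)
  mua
}

#' Solve the two-chromophore linear system
#'
#' Least-squares inversion of mu_a = E (C_HbO, C_Hb)' over >= 2 wavelengths;
#' with exactly two wavelengths this equals the exact 2x2 solve.
#'
#' @param mu_a numeric vector (one sample) or matrix (samples x wavelengths)
#'   of absorption coefficients, cm^-1
#' @param table an [extinction_table()]
#' @param wavelengths wavelengths corresponding to the columns of `mu_a`
#' @param cond_max maximum acceptable condition number of the extinction
#'   matrix before the system is declared singular
#' @return a [chromophore_state()]
#' @export
solve_two_chromophores <- function(mu_a, table = extinction_table(),
                                   wavelengths = table$wavelength_nm,
                                   cond_max = 1e8) {
  if (is.null(dim(mu_a))) mu_a <- matrix(mu_a, nrow = 1)
  abort_if(ncol(mu_a) < 2, "need absorption at >= 2 wavelengths")
  abort_if(ncol(mu_a) != length(wavelengths),
           "mu_a has %d columns but %d wavelengths given", ncol(mu_a), length(wavelengths))
  E <- extinction_matrix(table, wavelengths)
  abort_if(kappa(E, exact = TRUE) > cond_max,
           "extinction system is numerically singular (condition number > %g)", cond_max)
  cc <- qr.coef(qr(E), t(mu_a))  # 2 x n
  chromophore_state(unname(cc[1, ]), unname(cc[2, ]))
}
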