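#' Diffusion-limited apparent association rate
#'
#' Smoluchowski rate for an enzyme finding a DNA site by 3D diffusion,
#' scaled by the nuclear enzyme concentration to give the apparent
#' first-order binding rate:
#' `k_on = 4 * pi * (D_E + D_S) * (r_E + r_S) * n_E / V_nucleus`.
#' With `D_E ~ 3.8 um^2/s`, a negligible site diffusion coefficient,
#' 2.5 nm radii, 5000 enzymes and a 500 um^3 nucleus this gives the working
#' initiation/background rate of 2.4 s^-1.
#'
#' @param D_E Enzyme diffusion coefficient, um^2 s^-1.
#' @param D_S DNA-site diffusion coefficient, um^2 s^-1 (may be 0; a few
#'   orders of magnitude below `D_E` in practice).
#' @param r_E,r_S Enzyme and site radii, um.
#' @param n_E Number of enzymes per nucleus.
#' @param V_nucleus Nuclear volume, um^3.
#' @return Apparent first-order rate, s^-1.
#' @export
#' @examples
#' diffusion_limited_association(D_E = 3.8197, D_S = 0, r_E = 0.0025,
#'                               r_S = 0.0025, n_E = 5000, V_nucleus = 500)
diffusion_limited_association <- function(D_E, D_S, r_E, r_S, n_E,
                                          V_nucleus) {
  if (D_E < 0 || D_S < 0 || r_E <= 0 || r_S <= 0 || n_E <= 0 ||
      V_nucleus <= 0)
    abort("radii, enzyme count and volume must be positive; diffusion coefficients non-negative",
          class = "nucspread_domain_error")
  4 * pi * (D_E + D_S) * (r_E + r_S) * n_E / V_nucleus
}

#' 1D sliding hop rate between adjacent nucleosomes
#'
#' Maps a 1D sliding diffusion coefficient onto the discrete hop rate of the
#' lattice random walk, `k_slide = 2 * D_1d / d^2`, so that the walk's mean
#' squared displacement matches `2 * D * t`. With `D_1d = 2e-4 um^2/s` (the
#' low end of measured protein sliding on chromatin) and `d = 25 nm`
#' nucleosome spacing this gives 0.64 s^-1, the working value 0.6 s^-1.
#' This is the total hop rate over both directions; the simulator splits it
#' equally between the left and right sliding channels.
#'
#' @param D_1d 1D diffusion coefficient, um^2 s^-1.
#' @param d Nucleosome-to-nucleosome distance, um.
#' @return Total hop rate, s^-1.
#' @export
#' @examples
#' slide_rate(2e-4, 0.025)
slide_rate <- function(D_1d, d) {
  if (D_1d <= 0 || d <= 0)
    abort("`D_1d` and `d` must be positive", class = "nucspread_domain_error")
  2 * D_1d / d^2
}

#' Recruitment efficiency
#'
#' The dimensionless ratio of the lifetime of a modification
#' (`1 / k_demodification`) to the mean waiting time before a recruitment
#' event at a modified nucleosome (`1 / k_recruitment`):
#' `RE = k_recruitment / k_demodification`. `RE > 1` means a modified
#' nucleosome typically recruits an enzyme before losing its mark.
#'
#' @param k_recruitment Recruitment rate, s^-1.
#' @param k_demodification Demodification rate, s^-1.
#' @return Dimensionless efficiency.
#' @export
#' @examples
#' recruitment_efficiency(4.8, 2.4) # 2
#' recruitment_efficiency(1.2, 2.4) # 0.5
recruitment_efficiency <- function(k_recruitment, k_demodification) {
  if (k_recruitment <= 0 || k_demodification <= 0)
    abort("rates must be positive", class = "nucspread_domain_error")
  k_recruitment / k_demodification
}

#' Release rate from a mean residence time
#'
#' `k_off = 1 / residence_time`; a 10 s mean chromatin residence time (the
#' fast-fraction scale measured for HP1-type readers by FRAP) gives the
#' working release rate of 0.1 s^-1.
#'
#' @param residence_time Mean residence time, s.
#' @return Release rate, s^-1.
#' @export
#' @examples
#' off_rate_from_residence(10)
off_rate_from_residence <- function(residence_time) {
  if (residence_time <= 0)
    abort("`residence_time` must be positive",
          class = "nucspread_domain_error")
  1 / residence_time
}

#' Derive the working rate set from physical constants
#'
#' Regenerates the standard kinetic parameter table from its physical
#' inputs: the diffusion-limited association rate (initiation, background
#' acetylation and demodification), the residence-time release rate, and
#' the 1D-sliding hop rate.
#'
#' @param D_E Enzyme 3D diffusion coefficient, um^2 s^-1.
#' @param D_S Site diffusion coefficient, um^2 s^-1.
#' @param r_E,r_S Radii, um.
#' @param n_E Enzymes per nucleus.
#' @param V_nucleus Nuclear volume, um^3.
#' @param residence_time Mean chromatin residence time, s.
#' @param D_1d 1D sliding diffusion coefficient, um^2 s^-1.
#' @param d_spacing Nucleosome spacing, um.
#' @return A tibble with columns `parameter`, `value`, `units`, `origin`.
#' @export
derive_rate_table <- function(D_E = 3.8197, D_S = 0, r_E = 0.0025,
                              r_S = 0.0025, n_E = 5000, V_nucleus = 500,
                              residence_time = 10, D_1d = 2e-4,
                              d_spacing = 0.025) {
  k_assoc <- diffusion_limited_association(D_E, D_S, r_E, r_S, n_E, V_nucleus)
  tibble(
    parameter = c("k_on", "k_off", "k_slide", "k_demodification",
                  "k_background_acetylation"),
    value = c(k_assoc, off_rate_from_residence(residence_time),
              slide_rate(D_1d, d_spacing), k_assoc, k_assoc),
    units = "s^-1",
    origin = c("diffusion-limited association",
               "1 / residence time",
               "2 D / d^2 lattice hop",
               "diffusion-limited association (demodifying enzymes)",
               "diffusion-limited association (implicit acetyltransferase)"))
}
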