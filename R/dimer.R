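# Intradimer independence tests: whether a monomer's rotational state carries
# information about its dimer partner's state.

#' Intradimer rotational-state independence tests
#'
#' Two KS protocols on complete dimers (exactly two monomers, indices 0 and
#' 1); incomplete dimers are excluded and counted. F1 test: dimers are split
#' by the sign of monomer 0's F1-head angle and the partner (monomer 1) F1
#' distributions of the two groups are compared. Stalk test: monomer-0 stalk
#' angles within `mode_window` degrees of each dwell mode define three groups
#' of partner stalk distributions, compared pairwise. Under independent
#' monomers all p-values are uniform; perfectly correlated dimers drive them
#' to zero.
#'
#' @param t A [particle_table()] containing dimers.
#' @param mode_window Half-width (degrees) of the window around each mode.
#' @param modes Stalk dwell centres in degrees.
#' @return List with `f1_sign_p`, `stalk_mode_pairwise_p` (named, 3 values),
#'   `f1_group_n`, `stalk_group_n`, `n_dimers`, `n_excluded`, and logical
#'   `incomplete_groups` set when any group was empty (its p is `NA`).
#' @export
intradimer_tests <- function(t, mode_window = 30, modes = c(-120, 0, 120)) {
  need <- c("dimer_id", "monomer_index", "theta_f1", "theta_stalk")
  if (!all(need %in% names(t))) {
    stop("table lacks columns: ", paste(setdiff(need, names(t)), collapse = ", "),
         call. = FALSE)
  }
  d0 <- t[t$monomer_index == 0L, ]
  d1 <- t[t$monomer_index == 1L, ]
  common <- intersect(d0$dimer_id, d1$dimer_id)
  n_excluded <- length(unique(t$dimer_id)) - length(common)
  d0 <- d0[match(common, d0$dimer_id), ]
  d1 <- d1[match(common, d1$dimer_id), ]
  if (!length(common)) stop("no complete dimers in table", call. = FALSE)

  ks_p <- function(x, y) {
    if (!length(x) || !length(y)) return(NA_real_)
    suppressWarnings(stats::ks.test(x, y)$p.value)
  }

  pos <- d0$theta_f1 >= 0
  f1_groups <- list(positive = d1$theta_f1[pos], negative = d1$theta_f1[!pos])
  f1_p <- ks_p(f1_groups$positive, f1_groups$negative)

  stalk_groups <- lapply(modes, function(m) {
    d1$theta_stalk[abs(wrap_deg(d0$theta_stalk - m)) <= mode_window]
  })
  names(stalk_groups) <- paste0("mode_", modes)
  pairs <- utils::combn(length(modes), 2)
  stalk_p <- apply(pairs, 2, function(ij) {
    ks_p(stalk_groups[[ij[1]]], stalk_groups[[ij[2]]])
  })
  names(stalk_p) <- apply(pairs, 2, function(ij) {
    paste(names(stalk_groups)[ij], collapse = "_vs_")
  })

  list(f1_sign_p = f1_p,
       stalk_mode_pairwise_p = stalk_p,
       f1_group_n = lengths(f1_groups),
       stalk_group_n = lengths(stalk_groups),
       n_dimers = length(common),
       n_excluded = n_excluded,
       incomplete_groups = any(!lengths(f1_groups)) || any(!lengths(stalk_groups)))
}
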