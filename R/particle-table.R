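# ParticleTable: one row per monomer with ids and rotational / displacement
# state, exchanged as tab-separated text with a one-line header.

pt_required <- c("particle_id", "tomogram_id", "dimer_id", "monomer_index",
                 "theta_f1", "theta_stalk", "ups_disp")
pt_optional <- c("true_theta_f1", "true_theta_stalk", "true_ups_disp")

#' Validate a particle table
#'
#' Checks the ParticleTable contract: required columns present; all angles in
#' (-180, 180]; angles and displacements finite; each `dimer_id` occurs on at
#' most two rows with distinct `monomer_index` in \{0, 1\}; unique
#' `particle_id`.
#'
#' @param t A `data.frame` with one row per monomer.
#' @return The validated `data.frame` (invisibly classed `particle_table`).
#' @export
particle_table <- function(t) {
  if (!is.data.frame(t)) stop("particle table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(pt_required, names(t))
  if (length(missing_cols)) {
    stop("particle table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(t$particle_id)) {
    stop("duplicate particle_id values", call. = FALSE)
  }
  for (col in intersect(c("theta_f1", "theta_stalk", pt_optional[1:2]), names(t))) {
    v <- t[[col]]
    if (any(!is.finite(v))) stop("non-finite values in ", col, call. = FALSE)
    if (any(v <= -180 | v > 180)) {
      stop("angles in ", col, " must lie in (-180, 180]", call. = FALSE)
    }
  }
  if (any(!is.finite(t$ups_disp))) stop("non-finite ups_disp", call. = FALSE)
  if (!all(t$monomer_index %in% c(0L, 1L))) {
    stop("monomer_index must be 0 or 1", call. = FALSE)
  }
  key <- paste(t$dimer_id, t$monomer_index)
  if (anyDuplicated(key)) {
    stop("a dimer_id occurs more than once per monomer_index", call. = FALSE)
  }
  if (any(tabulate(factor(t$dimer_id)) > 2)) {
    stop("a dimer_id occurs on more than two rows", call. = FALSE)
  }
  class(t) <- unique(c("particle_table", class(t)))
  t
}

#' Write a particle table as tab-separated text
#'
#' @param t A [particle_table()] (validated on write).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(t, path) {
  t <- particle_table(as.data.frame(t))
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a particle table from tab-separated text
#'
#' @param path Input file path (one-line header, fixed column names).
#' @return A validated [particle_table()].
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  particle_table(utils::read.delim(path, sep = "\t", check.names = TRUE))
}
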