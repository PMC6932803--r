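# State-space layout.
#
# The immune arm is a 5 x (m+1) grid: rows are differentiation compartments
# (SCM, CM, EM, EFF, EXH), columns are senescence levels j = 0..m (the
# cumulative division count of the lineage).  The grid is followed by the
# two dendritic-cell pools, the tumor burden and the plasma drug
# concentration.  Internally the state is flattened column-major for the
# ODE solver.

#' Construct a model state
#'
#' @param T_grid 5 x (m+1) matrix of T-cell counts (rows SCM, CM, EM, EFF,
#'   EXH; columns senescence 0..m).
#' @param D_act,D_m activated and mature dendritic cells (cells).
#' @param C tumor burden (cells).
#' @param P plasma drug concentration (mg/L).
#' @return an object of class `icisim_state`.
#' @export
model_state <- function(T_grid, D_act = 0, D_m = 0, C = 0, P = 0) {
  T_grid <- as.matrix(T_grid)
  if (nrow(T_grid) != 5L)
    stop("T_grid must have 5 rows (SCM, CM, EM, EFF, EXH)")
  vals <- c(T_grid, D_act, D_m, C, P)
  if (any(!is.finite(vals))) stop("state entries must be finite")
  if (any(vals < 0)) stop("state entries must be non-negative")
  rownames(T_grid) <- COMPARTMENTS
  colnames(T_grid) <- as.character(seq_len(ncol(T_grid)) - 1L)
  structure(list(T_grid = T_grid, D_act = D_act, D_m = D_m, C = C, P = P),
            class = "icisim_state")
}

#' Uniformly seeded initial state
#'
#' Splits a total T-cell count equally over all 5 x (m+1) grid cells --
#' the uniform initial condition used for all patient simulations -- and
#' places the tumor and dendritic-cell pools.
#'
#' @param total_T total CD8+ T-cell count to spread over the grid (cells).
#' @param tumor0 initial tumor burden (cells).
#' @param dc0 initial count of each dendritic-cell pool (cells).
#' @param m senescence ceiling (number of levels is `m + 1`).
#' @return an `icisim_state` with `P = 0`.
#' @export
#' @examples
#' s <- initial_state(130, 1e9, 0, m = 25)
#' unique(as.vector(s$T_grid))  # every bin holds exactly 1 cell
initial_state <- function(total_T, tumor0, dc0 = 0, m = 25L) {
  if (any(c(total_T, tumor0, dc0) < 0))
    stop("initial cell counts must be non-negative")
  m <- as.integer(m)
  n_bins <- 5L * (m + 1L)
  T_grid <- matrix(total_T / n_bins, nrow = 5L, ncol = m + 1L)
  model_state(T_grid, D_act = dc0, D_m = dc0, C = tumor0, P = 0)
}

# Flatten to the solver vector: T grid (column-major), D_act, D_m, C, P.
pack_state <- function(state) {
  c(as.vector(state$T_grid), state$D_act, state$D_m, state$C, state$P)
}

unpack_state <- function(y, m) {
  nt <- 5L * (m + 1L)
  T_grid <- matrix(y[seq_len(nt)], nrow = 5L)
  rownames(T_grid) <- COMPARTMENTS
  colnames(T_grid) <- as.character(0:m)
  structure(list(T_grid = T_grid, D_act = y[nt + 1L], D_m = y[nt + 2L],
                 C = y[nt + 3L], P = y[nt + 4L]),
            class = "icisim_state")
}

state_length <- function(m) 5L * (m + 1L) + 4L

#' @export
print.icisim_state <- function(x, ...) {
  m <- ncol(x$T_grid) - 1L
  cat("Model state (m =", m, "):\n")
  cat("  T cells by compartment:",
      paste(sprintf("%s=%.4g", COMPARTMENTS, rowSums(x$T_grid)),
            collapse = " "), "\n")
  cat(sprintf("  D_act=%.4g D_m=%.4g C=%.6g cells P=%.4g mg/L\n",
              x$D_act, x$D_m, x$C, x$P))
  invisible(x)
}
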