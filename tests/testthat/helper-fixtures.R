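## Shared fixtures, built once per test run and cached. All fixtures are
## generated in code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

## small two-hemisphere atlas (6 labels/hemisphere, 162 vertices/hemisphere)
fx_atlas_small <- function() fx_cached("atlas_small", function()
  make_atlas_mesh(vertices_per_label = 25L, n_labels = 6L, seed = 42L))

## full-size atlas (34 labels/hemisphere, 2562 vertices/hemisphere)
fx_atlas_full <- function() fx_cached("atlas_full", function()
  make_atlas_mesh(vertices_per_label = 30L, n_labels = 34L, seed = 42L))

## spherical-shell phantom with solved potential and pial mesh
fx_shell <- function() fx_cached("shell", function() {
  vol <- make_shell_phantom(5, 7, 0.5)
  field <- solve_laplace(vol, tol = 1e-6)
  mesh <- icosphere(2, 7)
  list(vol = vol, field = field, mesh = mesh,
       map = compute_thickness(mesh, field, vol))
})

fx_slab <- function() fx_cached("slab", function() {
  vol <- make_slab_phantom(3, 1, 20)
  list(vol = vol, field = solve_laplace(vol, tol = 1e-6))
})

## closed-form harmonic potential of the spherical shell
shell_psi_exact <- function(r, r_inner = 5, r_outer = 7) {
  (1 / r_inner - 1 / r) / (1 / r_inner - 1 / r_outer)
}

## brute-force AUC oracle: pairwise positive-negative comparisons with
## ties counted one half
auc_pairwise <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
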