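# Shared toy objects, built in code.

cond_ref <- function() buffer_conditions(20, 7.0, 100)

# an apparent-constant table with directly injected K values (bypasses the
# correction chain, for solver-only tests)
toy_table <- function(K, conditions = cond_ref(), alpha = NULL) {
  if (is.null(alpha)) alpha <- stats::setNames(rep(1, ncol(K)), colnames(K))
  structure(list(kapp = K, alpha = alpha, conditions = conditions,
                 source = "toy"),
            class = "apparent_table")
}

toy_mixture <- function(mt, lt, conditions = cond_ref(),
                        modes = rep("total", length(mt))) {
  mixture_spec(
    chelators = lapply(names(lt), function(id) chelator_entry(id, lt[[id]])),
    metals = lapply(seq_along(mt), function(i)
      metal_entry(names(mt)[i], mt[[i]], mode = modes[i])),
    conditions = conditions
  )
}

# a Ca/EGTA-like single-ligand constant set as a JSON document
toy_set_json <- function(lk_ml = 10.86, pks = c(9.4, 8.8, 2.7, 2.0),
                         mhl = NULL, delta_h_ml = NULL) {
  prot <- paste(sprintf(
    '{"step": %d, "log_k": %s, "delta_h_kj_mol": null}',
    seq_along(pks), format(pks)), collapse = ", ")
  cx <- sprintf('{"metal": "Ca", "protons": 0, "log_k": %s, "delta_h_kj_mol": %s}',
                format(lk_ml),
                if (is.null(delta_h_ml)) "null" else format(delta_h_ml))
  if (!is.null(mhl))
    cx <- paste0(cx, sprintf(
      ', {"metal": "Ca", "protons": 1, "log_k": %s, "delta_h_kj_mol": null}',
      format(mhl)))
  sprintf('{
    "source": "custom", "citation": "toy",
    "metals": [{"id": "Ca", "charge": 2}],
    "ligands": [{
      "id": "EG", "charge": -4,
      "ref_temperature_c": 20, "ref_ionic_equivalence_mm": 100,
      "protonation": [%s],
      "complexes": [%s]
    }]
  }', prot, cx)
}
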