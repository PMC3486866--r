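# Reference LP oracle: scipy.optimize.linprog (HiGHS) through the system
# python, used to cross-check the package's simplex on random problems.
scipy_lp_script <- local({
  path <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "ub = [None if v < 0 else v for v in np.atleast_1d(d['ub'])]",
    "res = linprog(np.array(d['c']), A_eq=np.array(d['Aeq']),",
    "              b_eq=np.array(d['beq']), bounds=[(0, v) for v in ub],",
    "              method='highs')",
    "print(json.dumps({'status': int(res.status),",
    "                  'fun': res.fun if res.fun is not None else None}))"
  ), path)
  path
})

solve_lp_scipy <- function(obj, A, b, u, maximize = FALSE) {
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(c = as.numeric(if (maximize) -obj else obj),
         Aeq = unname(as.matrix(A)), beq = as.numeric(b),
         ub = ifelse(is.finite(u), u, -1)),
    inp, digits = NA, matrix = "rowmajor")
  out <- system2("python", c(scipy_lp_script, inp), stdout = TRUE)
  res <- jsonlite::fromJSON(out)
  status <- switch(as.character(res$status), "0" = "optimal",
                   "2" = "infeasible", "3" = "unbounded", "other")
  value <- if (status == "optimal") (if (maximize) -1 else 1) * res$fun
           else NA_real_
  list(status = status, value = value)
}
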