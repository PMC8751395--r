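"""Independent LP oracle used by the test suite.

Reads a JSON list of LPs (dense equality rows, optional inequality row,
box bounds) and solves each with scipy.optimize.linprog (HiGHS).
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

STATUS = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
          3: "unbounded", 4: "numerical_failure"}


def main(infile, outfile):
    probs = json.load(open(infile))
    out = []
    for p in probs:
        m, n = p["m"], p["n"]
        c = np.asarray(p["c"], dtype=float)
        sign = -1.0 if p.get("sense", "max") == "max" else 1.0
        A_eq = np.asarray(p["A_eq"], dtype=float).reshape(m, n) if m else None
        b_eq = np.asarray(p["b_eq"], dtype=float) if m else None
        A_ub = b_ub = None
        if "A_ub" in p:
            A_ub = np.asarray(p["A_ub"], dtype=float).reshape(-1, n)
            b_ub = np.atleast_1d(np.asarray(p["b_ub"], dtype=float))
        bounds = list(zip(p["lb"], p["ub"]))
        res = linprog(sign * c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                      bounds=bounds, method="highs")
        st = STATUS.get(res.status, "other")
        out.append({"status": st,
                    "obj": sign * res.fun if res.status == 0 else None})
    json.dump(out, open(outfile, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
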