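"""Batch 0/1 MILP solver backend on scipy.optimize.milp (HiGHS).

Reads a JSON file holding a list of models, solves each, writes a JSON list
of results. Model format (all indices 1-based, converted here):
  {"nvar": int, "obj": [...],
   "cons": {"i": [...], "j": [...], "v": [...], "lo": [...], "hi": [...]}}
Result: {"status": "optimal"|"infeasible"|"suboptimal"|"error",
         "objective": float|None, "x": [0/1 ints]|None}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_one(model):
    nvar = int(model["nvar"])
    c = np.asarray(model["obj"], dtype=float)
    cons = model.get("cons") or {}
    rows = np.asarray(cons.get("i", []), dtype=int) - 1
    cols = np.asarray(cons.get("j", []), dtype=int) - 1
    vals = np.asarray(cons.get("v", []), dtype=float)
    lo = np.asarray(cons.get("lo", []), dtype=float)
    hi = np.asarray(cons.get("hi", []), dtype=float)
    ncon = lo.size
    constraints = None
    if ncon:
        A = sparse.csc_matrix((vals, (rows, cols)), shape=(ncon, nvar))
        constraints = LinearConstraint(A, lo, hi)
    res = milp(
        c=c,
        constraints=constraints,
        integrality=np.ones(nvar),
        bounds=Bounds(0, 1),
        options={"mip_rel_gap": 0.0, "presolve": True},
    )
    if res.status == 0:
        x = np.rint(res.x).astype(int)
        return {"status": "optimal", "objective": float(c @ x),
                "x": x.tolist()}
    if res.status == 2:
        return {"status": "infeasible", "objective": None, "x": None}
    if res.status == 1 and res.x is not None:
        x = np.rint(res.x).astype(int)
        return {"status": "suboptimal", "objective": float(c @ x),
                "x": x.tolist()}
    return {"status": "error", "objective": None, "x": None}


def main(argv):
    infile, outfile = argv[1], argv[2]
    with open(infile) as fh:
        models = json.load(fh)
    results = [solve_one(m) for m in models]
    with open(outfile, "w") as fh:
        json.dump(results, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
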