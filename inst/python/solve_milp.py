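"""Solve a binary program described as JSON triplets with scipy's HiGHS MILP
interface. Input: spec JSON path; output: result JSON path.

Spec fields: nvar, ncon, obj, lb, ub, row, col, coef (0-based triplets),
rhs, sense ("<=" or "="), time_limit (seconds, -1 for none).
Result fields: status (0 optimal, 1 resource limit, 2 infeasible,
3 unbounded, 4 other), objective, x (rounded integer values), message.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(spec_path, out_path):
    with open(spec_path) as fh:
        spec = json.load(fh)
    nvar = int(spec["nvar"])
    ncon = int(spec["ncon"])
    obj = np.asarray(spec["obj"], dtype=float)
    lb = np.asarray(spec["lb"], dtype=float)
    ub = np.asarray(spec["ub"], dtype=float)
    row = np.asarray(spec["row"], dtype=int)
    col = np.asarray(spec["col"], dtype=int)
    coef = np.asarray(spec["coef"], dtype=float)
    rhs = np.asarray(spec["rhs"], dtype=float)
    sense = spec["sense"]

    A = sparse.csr_matrix((coef, (row, col)), shape=(ncon, nvar))
    cl = np.where([s == "=" for s in sense], rhs, -np.inf)
    cu = rhs
    options = {"mip_rel_gap": 0.0}
    tl = float(spec.get("time_limit", -1))
    if tl > 0:
        options["time_limit"] = tl
    res = milp(
        c=obj,
        constraints=LinearConstraint(A, cl, cu),
        integrality=np.ones(nvar),
        bounds=Bounds(lb, ub),
        options=options,
    )
    out = {
        "status": int(res.status),
        "objective": None if res.fun is None else float(res.fun),
        "x": [] if res.x is None else [int(v) for v in np.round(res.x)],
        "message": str(res.message),
    }
    with open(out_path, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
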