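"""Batched RDKit backend for the classrt R package.

Invoked as: python chem_backend.py <request.json> <response.json>

The request is a JSON object {"op": <name>, ...}; the response is a JSON
object. Molecule-level failures are reported as nulls so the caller can
apply its own drop/flag policy; malformed requests yield {"error": msg}.
JSON cannot carry NaN/Inf, so non-finite descriptor values are emitted as
null and re-masked on the R side.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonicalize(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": out}


def op_enumerate(req):
    # Up to k randomized renderings per molecule, each distinct as a string
    # from the canonical form and from each other, each canonicalizing back
    # to the parent. Retry budget 10*k as per the augmentation contract.
    k = int(req["k"])
    seeds = req["seeds"]
    out = []
    for smi, seed in zip(req["smiles"], seeds):
        m = _mol(smi)
        if m is None or k <= 0:
            out.append([])
            continue
        canon = Chem.MolToSmiles(m)
        budget = max(10 * k, 10)
        raw = Chem.MolToRandomSmilesVect(m, budget, randomSeed=int(seed))
        keep = []
        seen = {canon}
        for s in raw:
            if s in seen:
                continue
            m2 = Chem.MolFromSmiles(s)
            if m2 is None or Chem.MolToSmiles(m2) != canon:
                continue  # defensive; randomized rendering should round-trip
            seen.add(s)
            keep.append(s)
            if len(keep) == k:
                break
        out.append(keep)
    return {"variants": out}


def op_ecfp(req):
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 2048))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
        else:
            fp = gen.GetFingerprint(m)
            out.append(list(fp.GetOnBits()))
    return {"on_bits": out, "radius": radius, "nbits": nbits}


def op_compile_smarts(req):
    ok, err = [], []
    for pat in req["patterns"]:
        q = Chem.MolFromSmarts(pat)
        if q is None:
            ok.append(False)
            err.append("SMARTS failed to compile: %s" % pat)
        else:
            ok.append(True)
            err.append(None)
    return {"ok": ok, "msg": err}


def op_smarts_match(req):
    pats = []
    for i, pat in enumerate(req["patterns"]):
        q = Chem.MolFromSmarts(pat)
        if q is None:
            return {"error": "bad SMARTS at index %d: %s" % (i + 1, pat)}
        pats.append(q)
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
        else:
            out.append([bool(m.HasSubstructMatch(q)) for q in pats])
    return {"match": out}


def op_descriptors(req):
    names = [n for n, _ in Descriptors.descList]
    rows = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            rows.append(None)
            continue
        vals = Descriptors.CalcMolDescriptors(m)
        row = []
        for n in names:
            v = vals.get(n)
            if v is None or not isinstance(v, (int, float)) or not math.isfinite(v):
                row.append(None)
            else:
                row.append(float(v))
        rows.append(row)
    return {"names": names, "values": rows}


OPS = {
    "canonicalize": op_canonicalize,
    "enumerate": op_enumerate,
    "ecfp": op_ecfp,
    "compile_smarts": op_compile_smarts,
    "smarts_match": op_smarts_match,
    "descriptors": op_descriptors,
}


def main(argv):
    with open(argv[1]) as fh:
        req = json.load(fh)
    op = req.get("op")
    if op not in OPS:
        resp = {"error": "unknown op: %r" % op}
    else:
        try:
            resp = OPS[op](req)
        except Exception as exc:  # surfaced as an R error, not a crash
            resp = {"error": "%s: %s" % (type(exc).__name__, exc)}
    with open(argv[2], "w") as fh:
        json.dump(resp, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
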