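"""Dev-time generator: emits R/topology-data.R with per-residue internal
coordinate placement records derived from CCD ideal residue geometry
(via biotite), plus bond lists, chi torsion definitions and the
PDBv3<->CHARMM atom-name dialect table. Run from repo root:
    python data-raw/gen_topology.py > R/topology-data.R
"""
import sys
import numpy as np
import biotite.structure.info as info

AA = ["ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
      "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"]

CHI = {
    "ARG": [("N","CA","CB","CG"),("CA","CB","CG","CD"),("CB","CG","CD","NE"),("CG","CD","NE","CZ")],
    "ASN": [("N","CA","CB","CG"),("CA","CB","CG","OD1")],
    "ASP": [("N","CA","CB","CG"),("CA","CB","CG","OD1")],
    "CYS": [("N","CA","CB","SG")],
    "GLN": [("N","CA","CB","CG"),("CA","CB","CG","CD"),("CB","CG","CD","OE1")],
    "GLU": [("N","CA","CB","CG"),("CA","CB","CG","CD"),("CB","CG","CD","OE1")],
    "HIS": [("N","CA","CB","CG"),("CA","CB","CG","ND1")],
    "ILE": [("N","CA","CB","CG1"),("CA","CB","CG1","CD1")],
    "LEU": [("N","CA","CB","CG"),("CA","CB","CG","CD1")],
    "LYS": [("N","CA","CB","CG"),("CA","CB","CG","CD"),("CB","CG","CD","CE"),("CG","CD","CE","NZ")],
    "MET": [("N","CA","CB","CG"),("CA","CB","CG","SD"),("CB","CG","SD","CE")],
    "PHE": [("N","CA","CB","CG"),("CA","CB","CG","CD1")],
    "SER": [("N","CA","CB","OG")],
    "THR": [("N","CA","CB","OG1")],
    "TRP": [("N","CA","CB","CG"),("CA","CB","CG","CD1")],
    "TYR": [("N","CA","CB","CG"),("CA","CB","CG","CD1")],
    "VAL": [("N","CA","CB","CG1")],
}

DROP = {"OXT", "HXT", "H2", "H3"}  # terminal-variant atoms not modelled per-residue


def ang(a, b, c):
    u, v = a - b, c - b
    return float(np.degrees(np.arccos(np.clip(
        np.dot(u, v) / np.linalg.norm(u) / np.linalg.norm(v), -1, 1))))


def dih(a, b, c, d):
    b1, b2, b3 = b - a, c - b, d - c
    n1, n2 = np.cross(b1, b2), np.cross(b2, b3)
    y = np.dot(np.cross(n1, n2), b2 / np.linalg.norm(b2))
    return float(np.degrees(np.arctan2(y, np.dot(n1, n2))))


def fmt(x):
    return f"{x:.4f}"


def residue_entry(res):
    t = info.residue(res)
    keep = [i for i, n in enumerate(t.atom_name) if n not in DROP]
    names = [t.atom_name[i] for i in keep]
    elem = dict(zip(names, (t.element[i] for i in keep)))
    co = {t.atom_name[i]: t.coord[i].astype(float) for i in keep}
    # adjacency among kept atoms
    adj = {n: [] for n in names}
    bl = t.bonds.as_array()
    bonds = []
    for i, j, _ in bl:
        ni, nj = t.atom_name[i], t.atom_name[j]
        if ni in co and nj in co:
            adj[ni].append(nj)
            adj[nj].append(ni)
            bonds.append((ni, nj))
    # BFS from CA; synthetic parents for backbone root
    parent = {"CA": "N", "N": None}
    order = []
    queue = ["CA"]
    seen = {"CA", "N", "C", "O", "H"}  # backbone handled by hand ("H" = amide H)
    while queue:
        cur = queue.pop(0)
        for nb in sorted(adj[cur], key=names.index):
            if nb in seen or nb in parent:
                continue
            parent[nb] = cur
            order.append(nb)
            queue.append(nb)
    parent["C"] = "CA"
    # chi lookup: axis (q2,q3) -> (chi name, quadruple)
    chis = CHI.get(res, [])
    axis = {}
    for k, q in enumerate(chis):
        axis[(q[1], q[2])] = (f"chi{k+1}", q)
    rows = []

    def row(name, r1, r2, r3, bond, theta, kind, dval, dtor):
        rows.append((name, elem[name] if name in elem else "H",
                     r1, r2, r3, bond, theta, kind, dval, dtor))

    # backbone (constants independent of template; cross-residue refs "-X")
    row("N", "-C", "-CA", "-N", 1.329, 116.2, "tor", 0.0, "psi_prev")
    row("CA", "N", "-C", "-CA", 1.458, 121.7, "tor", 0.0, "omega_prev")
    row("C", "CA", "N", "-C", 1.525, 111.2, "tor", 0.0, "phi")
    row("O", "C", "CA", "N", 1.231, 120.8, "tor", 180.0, "psi")
    if res != "PRO":
        row("H", "N", "-C", "-O", 1.00, 119.0, "fixed", 180.0, "NA")
    for name in order:
        p = parent[name]
        if p == "CA":
            r2, r3 = "C", "N"
        else:
            r2 = parent[p]
            r3 = "N" if r2 == "CA" else parent[r2]
        d = dih(co[name], co[p], co[r2], co[r3])
        b = float(np.linalg.norm(co[name] - co[p]))
        a = ang(co[name], co[p], co[r2])
        key = (r2, p)
        if key in axis:
            tname, q = axis[key]
            off = d - dih(co[q[0]], co[q[1]], co[q[2]], co[q[3]])
            off = (off + 180.0) % 360.0 - 180.0
            row(name, p, r2, r3, b, a, "tor", off, tname)
        else:
            row(name, p, r2, r3, b, a, "fixed", d, "NA")
    return rows, bonds, chis


def main():
    out = sys.stdout
    out.write("# Amino-acid internal-coordinate topology tables.\n")
    out.write("# Generated from ideal residue geometry (chemical component\n")
    out.write("# dictionary); regenerate with data-raw/gen_topology.py.\n")
    out.write("# nolint start\n")
    out.write("..aa_topology <- list(\n")
    chunks = []
    for res in AA:
        rows, bonds, chis = residue_entry(res)
        p = []
        p.append(f"  {res} = list(\n    place = data.frame(\n")
        cols = list(zip(*rows))
        p.append("      name = c(%s),\n" % ", ".join('"%s"' % x for x in cols[0]))
        p.append("      element = c(%s),\n" % ", ".join('"%s"' % x for x in cols[1]))
        p.append("      r1 = c(%s),\n" % ", ".join('"%s"' % x for x in cols[2]))
        p.append("      r2 = c(%s),\n" % ", ".join('"%s"' % x for x in cols[3]))
        p.append("      r3 = c(%s),\n" % ", ".join('"%s"' % x for x in cols[4]))
        p.append("      bond = c(%s),\n" % ", ".join(fmt(x) for x in cols[5]))
        p.append("      angle = c(%s),\n" % ", ".join(fmt(x) for x in cols[6]))
        p.append("      dkind = c(%s),\n" % ", ".join('"%s"' % x for x in cols[7]))
        p.append("      dvalue = c(%s),\n" % ", ".join(fmt(x) for x in cols[8]))
        p.append("      dtor = c(%s),\n" % ", ".join(
            ("NA_character_" if x == "NA" else '"%s"' % x) for x in cols[9]))
        p.append("      stringsAsFactors = FALSE\n    ),\n")
        btxt = ", ".join('"%s","%s"' % (a, b) for a, b in bonds)
        p.append("    bonds = matrix(c(%s), ncol = 2, byrow = TRUE),\n" % btxt)
        if chis:
            ctxt = ",\n      ".join(
                'chi%d = c(%s)' % (k + 1, ", ".join('"%s"' % a for a in q))
                for k, q in enumerate(chis))
            p.append("    chis = list(\n      %s\n    )\n  )" % ctxt)
        else:
            p.append("    chis = list()\n  )")
        chunks.append("".join(p))
    out.write(",\n".join(chunks))
    out.write("\n)\n\n")

    # dialect table: pdb3 <-> charmm names, keyed by residue ("*" = any)
    rows = [("*", "H", "HN"), ("*", "OXT", "OT2"), ("ILE", "CD1", "CD")]
    for res in AA:
        t = info.residue(res)
        names = set(t.atom_name) - DROP
        for nm in sorted(names):
            # prochiral pairs: PDBv3 HX2/HX3 -> CHARMM HX1/HX2
            if nm.startswith("H") and nm.endswith("3") and nm[:-1] + "2" in names \
                    and nm[:-1] + "1" not in names:
                stem = nm[:-1]
                if res == "ILE" and stem == "HD1":
                    continue  # ILE HD11.. handled via CD1->CD rule below
                rows.append((res, stem + "2", stem + "1"))
                rows.append((res, stem + "3", stem + "2"))
        if res in ("SER", "CYS"):
            rows.append((res, "HG", "HG1"))
    for i in range(1, 4):
        rows.append(("ILE", f"HD1{i}", f"HD{i}"))
    out.write("..dialect_table <- data.frame(\n")
    out.write("  resname = c(%s),\n" % ", ".join('"%s"' % r[0] for r in rows))
    out.write("  pdb3 = c(%s),\n" % ", ".join('"%s"' % r[1] for r in rows))
    out.write("  charmm = c(%s),\n" % ", ".join('"%s"' % r[2] for r in rows))
    out.write("  stringsAsFactors = FALSE\n)\n")
    out.write("# nolint end\n")


if __name__ == "__main__":
    main()
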