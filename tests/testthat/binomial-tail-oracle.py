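# Independent exact oracle for the one-sided upper binomial tail.
#
# Reads whitespace-separated (N, N_i, N_j, N_ij) configurations from the
# file given as argv[1] and writes, to argv[2], the association-mode then
# dissociation-mode upper-tail p-values, one per line, computed in exact
# integer arithmetic: p = num / d**N with rational success probability a/d,
# num = sum_{k>=obs} C(N,k) a^k (d-a)^(N-k), converted to the nearest
# double only at the end.
import sys
from math import comb
from fractions import Fraction


def tail(obs, n, a, d):
    a = min(max(a, 0), d)
    num = sum(comb(n, k) * a**k * (d - a) ** (n - k) for k in range(obs, n + 1))
    return float(Fraction(num, d**n))


def main():
    with open(sys.argv[1]) as fh:
        cfgs = [tuple(map(int, line.split())) for line in fh if line.strip()]
    out = []
    for n, ni, nj, nij in cfgs:
        out.append(tail(nij, n, ni * nj, n * n))
    for n, ni, nj, nij in cfgs:
        rate_num = ni * (n - nj) + nj * (n - ni)
        out.append(tail(ni + nj - 2 * nij, n, rate_num, n * n))
    with open(sys.argv[2], "w") as fh:
        fh.write("\n".join(repr(v) for v in out) + "\n")


if __name__ == "__main__":
    main()
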