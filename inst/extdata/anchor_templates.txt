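residue SHA L
atom N N -C -CA -N 1.328 116.2 psi donor
atom CA C N -C -CA 1.458 121.7 omega none
atom C C CA N -C 1.525 111.2 phi none
atom O O C CA N 1.231 120.8 psi-180 acceptor
atom CB C CA N C 1.53 110.5 -122.6 none
atom CG C CB CA N 1.53 114.1 chi1 none
atom CD C CG CB CA 1.53 111.3 chi2 none
atom CE C CD CG CB 1.53 111.3 chi3 none
atom CZ C CE CD CG 1.53 111.3 chi4 none
atom SH S CZ CE CD 1.82 112 chi5 donor
residue DSH D
atom N N -C -CA -N 1.328 116.2 psi donor
atom CA C N -C -CA 1.458 121.7 omega none
atom C C CA N -C 1.525 111.2 phi none
atom O O C CA N 1.231 120.8 psi+180 acceptor
atom CB C CA N C 1.53 110.5 122.6 none
atom CG C CB CA N 1.53 114.1 chi1 none
atom CD C CG CB CA 1.53 111.3 chi2 none
atom CE C CD CG CB 1.53 111.3 chi3 none
atom CZ C CE CD CG 1.53 111.3 chi4 none
atom SH S CZ CE CD 1.82 112 chi5 donor
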