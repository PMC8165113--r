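sample_id	patient_id	sex	tissue
M001_nd	M001	M	nondiseased
M001_im	M001	M	intermediate
M001_ca	M001	M	calcified
M002_nd	M002	M	nondiseased
M002_im	M002	M	intermediate
M002_ca	M002	M	calcified
M003_nd	M003	M	nondiseased
M003_im	M003	M	intermediate
M003_ca	M003	M	calcified
M004_nd	M004	M	nondiseased
M004_im	M004	M	intermediate
M004_ca	M004	M	calcified
M005_nd	M005	M	nondiseased
M005_im	M005	M	intermediate
M005_ca	M005	M	calcified
F001_nd	F001	F	nondiseased
F001_im	F001	F	intermediate
F001_ca	F001	F	calcified
F002_nd	F002	F	nondiseased
F002_im	F002	F	intermediate
F002_ca	F002	F	calcified
F003_nd	F003	F	nondiseased
F003_im	F003	F	intermediate
F003_ca	F003	F	calcified
F004_nd	F004	F	nondiseased
F004_im	F004	F	intermediate
F004_ca	F004	F	calcified
F005_nd	F005	F	nondiseased
F005_im	F005	F	intermediate
F005_ca	F005	F	calcified
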