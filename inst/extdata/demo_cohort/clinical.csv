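patient_id,sex,age,bmi,cabg,diabetes,ckd,smoking
M001,M,61.4186930247647,22.9011317317856,1,1,1,former
M002,M,73.6221324890597,35.4674008368309,0,0,0,former
M003,M,68.9474736149258,36.287608284767,1,1,0,former
M004,M,63.7936456004443,27.7281162449211,1,0,1,never
M005,M,86.4710397772973,36.3907136003152,1,0,0,former
F001,F,79.5029495397999,19.1858234767574,0,0,1,never
F002,F,80.3236591741601,37.8672189966679,0,0,1,former
F003,F,76.6655256755622,32.4795779424327,1,0,0,never
F004,F,82.9165795038237,38.3460183850428,0,0,1,former
F005,F,86.7156738471185,22.8573524910618,0,0,1,never
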