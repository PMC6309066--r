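disease	comorbidity	source
obesity	hypertension	CDC
obesity	coronary heart disease	CDC
obesity	stroke	CDC
obesity	dyslipidemia	CDC
obesity	type 2 diabetes	CDC
obesity	gallbladder disease	CDC
obesity	osteoarthritis	CDC
obesity	sleep apnea	CDC
obesity	breathing problems	CDC
obesity	endometrial cancer	CDC
obesity	breast cancer	CDC
obesity	colon cancer	CDC
obesity	kidney cancer	CDC
obesity	gallbladder cancer	CDC
obesity	liver cancer	CDC
obesity	depression	CDC
obesity	anxiety	CDC
psoriasis	cardiac event	National Psoriasis Foundation
psoriasis	stroke	National Psoriasis Foundation
psoriasis	crohn's disease	National Psoriasis Foundation
psoriasis	diabetes	National Psoriasis Foundation
psoriasis	metabolic syndrome	National Psoriasis Foundation
psoriasis	obesity	National Psoriasis Foundation
psoriasis	osteoporosis	National Psoriasis Foundation
psoriasis	uveitis	National Psoriasis Foundation
psoriasis	liver disease	National Psoriasis Foundation
psoriasis	cancer	National Psoriasis Foundation
psoriasis	depression	National Psoriasis Foundation
multiple sclerosis	spasticity	National Multiple Sclerosis Society
multiple sclerosis	bladder disorder	National Multiple Sclerosis Society
multiple sclerosis	bowel problem	National Multiple Sclerosis Society
multiple sclerosis	vision problem	National Multiple Sclerosis Society
multiple sclerosis	fatigue	National Multiple Sclerosis Society
multiple sclerosis	weakness	National Multiple Sclerosis Society
multiple sclerosis	chronic lung disease	literature report
multiple sclerosis	hypertension	literature report
multiple sclerosis	diabetes	literature report
multiple sclerosis	numbness	National Multiple Sclerosis Society
multiple sclerosis	sexual problem	National Multiple Sclerosis Society
multiple sclerosis	pain	National Multiple Sclerosis Society
multiple sclerosis	headache	National Multiple Sclerosis Society
multiple sclerosis	epilepsy	National Multiple Sclerosis Society
multiple sclerosis	cognitive problem	National Multiple Sclerosis Society
multiple sclerosis	seizure	National Multiple Sclerosis Society
multiple sclerosis	tremor	National Multiple Sclerosis Society
multiple sclerosis	depression	National Multiple Sclerosis Society
multiple sclerosis	bipolar disorder	National Multiple Sclerosis Society
multiple sclerosis	anxiety	National Multiple Sclerosis Society
multiple sclerosis	schizophrenia	National Multiple Sclerosis Society
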