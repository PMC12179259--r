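name,input_kind,form,a,b,citation,notes
hildebrand_lm,raw_accel_enmo,linear_vo2,7.28,0.032,"Hildebrand M et al. (2014) Med Sci Sports Exerc 46(9):1816-1824, wrist ActiGraph adults: VO2 = 0.0320*ENMO + 7.28 ml/kg/min","MET = VO2/3.5; ENMO in mg"
hildebrand_nlm,raw_accel_enmo,power_vo2,0.901,0.534,"Hildebrand M et al. (2017) Scand J Med Sci Sports 27(12):1814-1823 (nonlinear update)","synthetic placeholder coefficients for the power form VO2 = a*ENMO^b; edit to the calibration of the cited work before substantive use"
freedson,counts_per_min,linear,1.439008,0.000795,"Freedson PS, Melanson E, Sirard J (1998) Med Sci Sports Exerc 30(5):777-781, vertical-axis counts/min (hip)","METs = 1.439008 + 0.000795*CPM"
sasaki,counts_per_min,linear,0.668876,0.000863,"Sasaki JE, John D, Freedson PS (2011) J Sci Med Sport 14(5):411-416, vector-magnitude counts/min (hip)","METs = 0.000863*VM3 + 0.668876"
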