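patient_id,gp_id,birth_year,sex,test_code,date,year,test_name,num1,num2,unit
27898,GP_98,1957,F,S00000057,09/08/2014,2014,,1650,,cm
27898,GP_98,1957,F,S00000058,09/08/2014,2014,,56.50,,kg
27898,GP_98,1957,F,S00000057,29/09/1995,1995,Height,1630,,S002
27898,GP_98,1957,F,S00000058,29/09/1995,1995,Weight,610,,S006
42716,GP_98,1963,M,S00000069,18/11/2013,2013,,113,88,mmHg
61905,GP_98,1964,F,S00000069,16/08/1993,1993,Blood pressure,90,50,mmHg
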