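rt_list,mean_rt,formula,polymer,mean_experimental_mass,mean_ppm_error,doubly_charged
4.68;4.72;5.31;5.63,5.09,C30H26O12,Cat-Cat,578.1401,4.0,FALSE
6.01;6.38;7.05,6.48,C30H26O13,Cat-GalCat,594.1308,11.0,FALSE
8.03,8.03,C30H26O14,GalCat-GalCat,610.1264,9.6,FALSE
5.78;6.09;6.59,6.15,C37H30O16,Cat-Cat:Gal,730.1480,7.4,FALSE
7.04;7.24;7.44;7.61;7.72;7.97;8.12;8.42;8.86,7.82,C45H38O18,Cat-Cat-Cat,866.2011,5.4,FALSE
7.24;7.85;8.30;8.49;8.74;9.01;9.13;9.32;9.69;10.04,8.78,C45H38O19,Cat-Cat-GalCat,882.1940,7.6,FALSE
7.03;9.49;9.77;10.00;10.30;10.46,9.51,C45H38O20,Cat-GalCat-GalCat,898.1860,10.7,FALSE
7.22;7.46;7.65;7.95;8.15;8.39;8.66;8.77,8.03,C52H42O22,Cat-Cat-Cat:Gal,1018.2106,6.1,FALSE
8.65;9.13;9.41;9.59;9.85;10.14;10.32;10.69,9.72,C60H50O24,Cat-Cat-Cat-Cat,1154.2613,6.8,FALSE
10.54;10.70;10.89;11.29;11.58;11.86,11.14,C60H50O25,Cat-Cat-Cat-GalCat,1170.2537,8.9,TRUE
11.62;12.10;12.45;12.69;12.94,12.36,C60H50O26,Cat-Cat-GalCat-GalCat,1186.2434,13.2,TRUE
13.69;13.95;14.20,13.95,C60H50O27,Cat-GalCat-GalCat-GalCat,1202.2393,12.2,TRUE
9.70;9.86;10.09;10.45;10.72;10.88;11.02,10.31,C67H54O28,Cat-Cat-Cat-Cat:Gal,1306.2720,6.2,TRUE
11.68,11.68,C67H54O29,Cat-Cat-Cat-GalCat:Gal,1322.2583,12.7,TRUE
11.77;11.91;12.02;12.31,12.00,C75H62O30,Cat-Cat-Cat-Cat-Cat,1442.3256,4.8,TRUE
13.07;13.38,13.23,C75H62O31,Cat-Cat-Cat-Cat-GalCat,1458.3216,4.0,TRUE
14.75,14.75,C75H62O32,Cat-Cat-Cat-GalCat-GalCat,1474.3129,6.5,TRUE
15.8;16.06,15.93,C75H62O33,Cat-Cat-GalCat-GalCat-GalCat,1490.2938,15.8,TRUE
13.66;13.88;14.09;14.27,13.98,C90H74O36,Cat-Cat-Cat-Cat-Cat-Cat,1730.3864,5.5,TRUE
14.6,14.60,C97H78O40,Cat-Cat-Cat-Cat-Cat-Cat:Gal,1882.3969,5.3,TRUE
15.77,15.77,C105H86O42,Cat-Cat-Cat-Cat-Cat-Cat-Cat,2018.4477,5.8,TRUE
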