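feature,normal_vs_abnormal,fibrocystic_vs_metastatic
cell_volume,Yes,Yes
nuclear_volume,Yes,Yes
nucleus_to_cytoplasm_ratio,Yes,Yes
nuclear_sphericity,Yes,Yes
number_of_nucleoli,Yes,No
total_nucleolar_volume,No,No
variance_in_nucleolar_volume,Yes,No
average_nucleolar_margination,Yes,No
variance_in_nucleolar_margination,Yes,Yes
total_nuclear_content,Yes,Yes
mean_nuclear_content,Yes,Yes
variance_in_nuclear_content,Yes,No
skew_in_nuclear_content,Yes,No
kurtosis_in_nuclear_content,Yes,Yes
low_density_volume_fraction,Yes,No
medium_density_volume_fraction,Yes,Yes
high_density_volume_fraction,Yes,No
low_density_content_fraction,Yes,Yes
medium_density_content_fraction,Yes,Yes
high_density_content_fraction,Yes,Yes
number_of_low_density_clumps,Yes,Yes
number_of_medium_density_clumps,Yes,Yes
number_of_high_density_clumps,Yes,Yes
low_density_compactness,Yes,Yes
medium_density_compactness,Yes,No
high_density_compactness,Yes,Yes
medium_high_density_compactness,Yes,Yes
average_extinction_ratio_low_medium,Yes,No
average_extinction_ratio_low_high,Yes,Yes
average_extinction_ratio_low_medium_high,Yes,Yes
average_distance_from_nucleus_center_to_low_density_regions,Yes,Yes
average_distance_from_nucleus_center_to_medium_density_regions,No,Yes
average_distance_from_nucleus_center_to_high_density_regions,Yes,Yes
average_distance_from_nucleus_center_to_medium_high_density_regions,Yes,Yes
average_centroidal_distance_from_nucleus_center_to_low_density_regions,Yes,Yes
average_centroidal_distance_from_nucleus_center_to_medium_density_regions,No,No
average_centroidal_distance_from_nucleus_center_to_high_density_regions,Yes,No
average_centroidal_distance_from_nucleus_center_to_medium_high_density_regions,No,No
markovian_contrast,Yes,Yes
markovian_correlation,Yes,Yes
markovian_energy,Yes,Yes
markovian_heterogeneity,Yes,Yes
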